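#' Read a twin-pair table from CSV/TSV
#'
#' Delimiter is inferred from the extension (`.tsv` = tab, otherwise
#' comma). The table is validated: metadata columns present, every pair
#' complete with twin indices 1 and 2, both members sharing zygosity and
#' gender, zygosity in {MZ, DZ} and gender in {F, M}. When a registry is
#' given, variable columns are checked and reordered to registry order.
#'
#' @param path File path.
#' @param registry Optional variable registry.
#' @return A validated twin-pair `data.frame`.
#' @export
read_twin_table <- function(path, registry = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(.meta_cols, names(tab))
  if (length(missing)) stop("missing required columns: ",
                            paste(missing, collapse = ", "))
  tab$pair_id <- as.character(tab$pair_id)
  bad_z <- setdiff(unique(tab$zygosity), c("MZ", "DZ"))
  if (length(bad_z)) stop("unknown zygosity codes: ", paste(bad_z, collapse = ", "))
  bad_g <- setdiff(unique(tab$gender), c("F", "M"))
  if (length(bad_g)) stop("unknown gender codes: ", paste(bad_g, collapse = ", "))
  if (anyDuplicated(tab[, c("pair_id", "twin_index")])) {
    stop("duplicate pair_id/twin_index rows")
  }
  cnt <- table(tab$pair_id)
  if (any(cnt != 2)) {
    stop("incomplete pairs: ", paste(utils::head(names(cnt)[cnt != 2], 5),
                                     collapse = ", "))
  }
  hom <- tapply(paste(tab$zygosity, tab$gender), tab$pair_id,
                function(z) length(unique(z)) == 1L)
  if (!all(hom)) {
    stop("pairs with discordant zygosity/gender: ",
         paste(utils::head(names(hom)[!hom], 5), collapse = ", "))
  }
  vars <- setdiff(names(tab), .meta_cols)
  if (!is.null(registry)) {
    validate_registry(registry)
    missing_v <- setdiff(registry$name, vars)
    if (length(missing_v)) stop("missing registry variables: ",
                                paste(missing_v, collapse = ", "))
    tab <- tab[, c(.meta_cols, registry$name)]
  }
  for (v in setdiff(names(tab), .meta_cols)) {
    if (!is.numeric(tab[[v]])) stop("non-numeric variable column: ", v)
  }
  tab
}

#' Write a twin-pair table to CSV/TSV
#'
#' @param table The twin-pair table.
#' @param path Output path; `.tsv` writes tab-separated, else comma.
#' @return The path, invisibly.
#' @export
write_twin_table <- function(table, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(table, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Export a network model
#'
#' Three formats: a weighted edge list TSV (`node_i`, `node_j`,
#' `weight`, full precision, nonzero edges only), a square weight-matrix
#' CSV (lossless round trip), and GraphML with node category attributes
#' for import into Cytoscape-style viewers.
#'
#' @param model A `network_model` or a weight matrix.
#' @param path Output file path.
#' @param format `"edgelist"`, `"matrix"` or `"graphml"`.
#' @param registry Optional registry supplying node categories for
#'   GraphML.
#' @return The path, invisibly.
#' @export
write_network <- function(model, path,
                          format = c("edgelist", "matrix", "graphml"),
                          registry = NULL) {
  format <- match.arg(format)
  W <- .as_weight_matrix(model)
  labels <- colnames(W)
  if (is.null(labels)) labels <- paste0("V", seq_len(ncol(W)))
  if (format == "matrix") {
    out <- as.data.frame(W)
    names(out) <- labels
    utils::write.table(cbind(node = labels, format(out, digits = 17)),
                       path, sep = ",", row.names = FALSE, quote = FALSE)
  } else if (format == "edgelist") {
    ut <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
    el <- data.frame(node_i = labels[ut[, 1]], node_j = labels[ut[, 2]],
                     weight = format(W[ut], digits = 17))
    if (nrow(ut) == 0) el <- el[0, ]
    utils::write.table(el, path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    .write_graphml(W, labels, path, registry)
  }
  invisible(path)
}

#' Read a weight matrix written by `write_network(format = "matrix")`
#'
#' @param path CSV path.
#' @return Numeric matrix with node dimnames.
#' @export
read_network_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = ",",
                           stringsAsFactors = FALSE, check.names = FALSE)
  labels <- tab$node
  W <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(W) <- list(labels, labels)
  W
}

.write_graphml <- function(W, labels, path, registry = NULL) {
  category <- rep("unknown", length(labels))
  if (!is.null(registry)) {
    validate_registry(registry)
    idx <- match(labels, registry$name)
    category[!is.na(idx)] <- registry$category[idx[!is.na(idx)]]
  }
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns",
    "xmlns:xsi" = "http://www.w3.org/2001/XMLSchema-instance",
    "xsi:schemaLocation" = paste(
      "http://graphml.graphdrawing.org/xmlns",
      "http://graphml.graphdrawing.org/xmlns/1.0/graphml.xsd")
  )
  key_n <- xml2::xml_add_child(doc, "key", id = "d0", `for` = "node",
                               attr.name = "category", attr.type = "string")
  key_e <- xml2::xml_add_child(doc, "key", id = "d1", `for` = "edge",
                               attr.name = "weight", attr.type = "double")
  g <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "undirected")
  for (i in seq_along(labels)) {
    nd <- xml2::xml_add_child(g, "node", id = labels[i])
    dt <- xml2::xml_add_child(nd, "data", key = "d0")
    xml2::xml_text(dt) <- category[i]
  }
  idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    e <- xml2::xml_add_child(g, "edge",
                             source = labels[idx[k, 1]],
                             target = labels[idx[k, 2]])
    dt <- xml2::xml_add_child(e, "data", key = "d1")
    xml2::xml_text(dt) <- format(W[idx[k, 1], idx[k, 2]], digits = 17)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write / read a precision matrix as square CSV
#'
#' Used to export ground-truth matrices for external checks.
#'
#' @param Theta Square matrix.
#' @param path CSV path.
#' @return The path (write) or the matrix (read).
#' @export
write_precision_csv <- function(Theta, path) {
  utils::write.table(format(Theta, digits = 17), path, sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_precision_csv
#' @export
read_precision_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}
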