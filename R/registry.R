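#' The default 39-node variable registry
#'
#' The node battery covers nine depressive symptoms, six cognitive test
#' scores, the reported frequency of eight intellectual, six physical and
#' eight social leisure activities, and two covariates (age and alcohol
#' consumption). The registry fixes the variable order used for every
#' matrix row/column downstream, so all weight matrices, centrality tables
#' and exported networks index nodes identically.
#'
#' @param p Optional number of generic nodes. When supplied, a registry of
#'   `p` continuous variables named `V01, V02, ...` (all category
#'   `"generic"`) is returned instead of the default battery; this is the
#'   form used for simulation studies that do not need the full battery.
#' @return A data frame with columns `name`, `category` (one of
#'   `depressive`, `cognitive`, `intellectual`, `physical`, `social`,
#'   `covariate`, or `generic`) and `scale` (`continuous`, `count`, or
#'   `frequency`).
#' @examples
#' reg <- variable_registry()
#' table(reg$category)
#' @export
variable_registry <- function(p = NULL) {
  if (!is.null(p)) {
    stopifnot(is.numeric(p), length(p) == 1L, p >= 2)
    return(data.frame(
      name = sprintf("V%02d", seq_len(p)),
      category = "generic",
      scale = "continuous",
      stringsAsFactors = FALSE
    ))
  }
  entry <- function(names, category, scale) {
    data.frame(name = names, category = category, scale = scale,
               stringsAsFactors = FALSE)
  }
  reg <- rbind(
    entry(c("Sad", "HappyNow", "Lonely", "WorthNothing", "Outlook",
            "Tension", "Tired", "Restless", "Irritable"),
          "depressive", "count"),
    entry(c("Learning", "DelayedRecall", "WorkingMemory", "Fluency",
            "DigitSpan", "ProcessingSpeed"),
          "cognitive", "continuous"),
    entry(c("Museum", "Library", "Courses", "WriteStory", "Reading",
            "Crossword", "Concert", "Lecture"),
          "intellectual", "frequency"),
    entry(c("Exercised", "Biking", "StrenuousSport", "Walking",
            "Gardening", "HardWork"),
          "physical", "frequency"),
    entry(c("MeetTwin", "PhoneTwin", "CallFamily", "VisitDinner",
            "MeetFriends", "PhoneFriends", "Guests", "ClubMeeting"),
          "social", "frequency"),
    entry(c("Age", "Alcohol"), "covariate", "continuous")
  )
  rownames(reg) <- NULL
  validate_registry(reg)
  reg
}

#' Validate a variable registry
#'
#' Checks uniqueness of names and well-formedness of categories. Called by
#' every entry point that accepts a registry override.
#'
#' @param registry A data frame as returned by [variable_registry()].
#' @return The registry, invisibly, if valid; otherwise an error.
#' @export
validate_registry <- function(registry) {
  stopifnot(is.data.frame(registry))
  req <- c("name", "category", "scale")
  if (!all(req %in% names(registry))) {
    stop("registry must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(registry$name)) {
    stop("registry variable names must be unique")
  }
  ok_cat <- c("depressive", "cognitive", "intellectual", "physical",
              "social", "covariate", "generic")
  bad <- setdiff(unique(registry$category), ok_cat)
  if (length(bad)) stop("unknown registry categories: ",
                        paste(bad, collapse = ", "))
  if (nrow(registry) < 2) stop("registry needs at least 2 variables")
  invisible(registry)
}

# metadata columns that precede the variables in every twin table
.meta_cols <- c("pair_id", "twin_index", "zygosity", "gender")
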