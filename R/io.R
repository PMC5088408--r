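# Readers and writers: wide ratings CSV, profile CSV/JSON, sidecar YAML.
#
# CSV dialect: comma-separated, UTF-8, LF line endings, header row, quoting
# only when needed.  In the ratings dialect the first column is `cell_id`,
# each further column one rater; an empty cell is a missing rating.

#' Read a wide-format ratings CSV
#'
#' @param path CSV file: first column `cell_id`, one column per rater,
#'   empty cells for missing ratings; tokens must belong to the five-way
#'   rating vocabulary.
#' @param sidecar Optional YAML file with keys `rater_experience` (map
#'   rater id -> experienced/inexperienced) and `unit_test` (map cell id ->
#'   test tag).
#' @return A [ratings_table()].
#' @export
read_ratings_csv <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (!"cell_id" %in% names(df)) {
    stop("parse error: ratings CSV must have a 'cell_id' first column")
  }
  if (anyDuplicated(df$cell_id)) {
    stop("parse error: duplicate cell_id '",
         df$cell_id[duplicated(df$cell_id)][1], "'")
  }
  raters <- setdiff(names(df), "cell_id")
  vals <- as.matrix(df[, raters, drop = FALSE])
  vals[vals == ""] <- NA_character_
  rownames(vals) <- df$cell_id
  cats <- rating_labels()
  for (j in seq_along(raters)) {
    bad <- which(!is.na(vals[, j]) & !(vals[, j] %in% cats))
    if (length(bad) > 0) {
      stop(sprintf(
        "parse error: unknown token '%s' at row %d, column '%s'",
        vals[bad[1], j], bad[1], raters[j]))
    }
  }
  experience <- NULL
  unit_test <- NULL
  if (!is.null(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    if (!is.null(meta$rater_experience)) {
      experience <- unlist(meta$rater_experience)
    }
    if (!is.null(meta$unit_test)) {
      ut <- unlist(meta$unit_test)
      unit_test <- unname(ut[rownames(vals)])
    }
  }
  ratings_table(vals, rater_experience = experience, unit_test = unit_test)
}

#' Write a ratings table as wide CSV
#'
#' @param ratings A [ratings_table()].
#' @param path Output file.
#' @param sidecar Optional path for a YAML sidecar holding rater experience
#'   and unit test tags (written only when metadata are present).
#' @return `path`, invisibly.
#' @export
write_ratings_csv <- function(ratings, path, sidecar = NULL) {
  stopifnot(inherits(ratings, "ratings_table"))
  v <- ratings$values
  df <- data.frame(cell_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE,
                   eol = "\n", fileEncoding = "UTF-8")
  if (!is.null(sidecar) &&
      (!is.null(ratings$rater_experience) || !is.null(ratings$unit_test))) {
    meta <- list()
    if (!is.null(ratings$rater_experience)) {
      meta$rater_experience <- as.list(ratings$rater_experience)
    }
    if (!is.null(ratings$unit_test)) {
      meta$unit_test <- as.list(ratings$unit_test)
    }
    yaml::write_yaml(meta, sidecar)
  }
  invisible(path)
}

#' Read and write profile tables
#'
#' Profile CSVs have one row per cell, columns named after the profile
#' fields, tokens from the controlled vocabulary and accessory flags as a
#' `";"`-separated string (empty for none).  The JSON dialect is an array of
#' objects, one per cell, with `accessory_flags` as a JSON array.  Reading
#' validates every record.
#'
#' @param path File path.
#' @param validate Logical; run every row through [validate_profile()]
#'   (default `TRUE`).
#' @return Data frame of profiles (extra columns such as `true_fine` or
#'   `cell_id` are preserved).
#' @export
read_profiles_csv <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"accessory_flags" %in% names(df)) df$accessory_flags <- ""
  df$accessory_flags[is.na(df$accessory_flags)] <- ""
  if (validate) {
    for (i in seq_len(nrow(df))) {
      validate_profile(df[i, , drop = FALSE])
    }
  }
  df
}

#' @rdname read_profiles_csv
#' @param profiles Data frame of profiles.
#' @export
write_profiles_csv <- function(profiles, path) {
  utils::write.csv(profiles, path, row.names = FALSE, na = "", quote = FALSE,
                   eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_profiles_csv
#' @export
read_profiles_json <- function(path, validate = TRUE) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  profs <- lapply(recs, function(r) {
    r$accessory_flags <- unlist(r$accessory_flags)
    if (validate) r <- unclass(validate_profile(r))
    r$accessory_flags <- paste(r$accessory_flags, collapse = ";")
    extra <- setdiff(names(r), profile_fields())
    as.data.frame(c(r[profile_fields()], r[extra]), stringsAsFactors = FALSE)
  })
  do.call(rbind, profs)
}

#' @rdname read_profiles_csv
#' @export
write_profiles_json <- function(profiles, path) {
  recs <- lapply(seq_len(nrow(profiles)), function(i) {
    r <- as.list(profiles[i, , drop = FALSE])
    fl <- r$accessory_flags
    r$accessory_flags <- if (is.character(fl) && nzchar(fl) && !is.na(fl)) {
      strsplit(fl, ";")[[1]]
    } else character(0)
    r
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
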