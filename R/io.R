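#' Build a validated table of replicated PO assay readings
#'
#' A `po_table` holds OD520 phenol-oxidase readings either for pairwise
#' mixed-hemocyte incubations (two individual IDs per row) or for
#' antibody stimulation of single individuals, in which case `subject_b`
#' carries the stimulus tag `"mAb"`. Pairs are unordered: the two
#' suspensions are mixed symmetrically, so rows are canonicalized with
#' the lexicographically smaller ID first.
#'
#' @param df A data.frame with columns `subject_a`, `subject_b`,
#'   `replicate`, `od520`.
#' @return A data.frame of class `po_table` with canonicalized pairs.
#' @examples
#' po_table(data.frame(subject_a = "B", subject_b = "A",
#'                     replicate = 1, od520 = 0.2))
#' @export
po_table <- function(df) {
  req <- c("subject_a", "subject_b", "replicate", "od520")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  df <- df[req]
  df$subject_a <- as.character(df$subject_a)
  df$subject_b <- as.character(df$subject_b)
  df$replicate <- as.integer(df$replicate)
  df$od520 <- as.numeric(df$od520)

  bad <- which(is.na(df$od520) | df$od520 < 0)
  if (length(bad))
    stop("negative or missing od520 in row(s): ", paste(bad, collapse = ", "))
  bad <- which(is.na(df$replicate) | df$replicate < 1)
  if (length(bad))
    stop("replicate index must be a positive integer; row(s): ",
         paste(bad, collapse = ", "))

  # canonical pair order: smaller ID first (mAb rows keep the subject in a)
  pair <- df$subject_b != "mAb"
  swap <- pair & df$subject_b < df$subject_a
  tmp <- df$subject_a[swap]
  df$subject_a[swap] <- df$subject_b[swap]
  df$subject_b[swap] <- tmp

  key <- paste(df$subject_a, df$subject_b, df$replicate, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (pair, replicate) after canonicalization in row(s): ",
         paste(dup, collapse = ", "))
  rownames(df) <- NULL
  class(df) <- c("po_table", "data.frame")
  df
}

#' Read a PO assay table from TSV or CSV
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param col_map Optional named character vector mapping the canonical
#'   column names (`subject_a`, `subject_b`, `replicate`, `od520`) to the
#'   names used in the file.
#' @return A `po_table`.
#' @seealso [write_po_table()]
#' @export
read_po_table <- function(path, dialect = c("tsv", "csv"), col_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  df <- remap_columns(df, col_map,
                      c("subject_a", "subject_b", "replicate", "od520"))
  po_table(df)
}

#' Write a PO assay table
#'
#' @param x A `po_table`.
#' @param path Output file path.
#' @param dialect `"tsv"` or `"csv"`.
#' @export
write_po_table <- function(x, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  utils::write.table(as.data.frame(x), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

remap_columns <- function(df, col_map, required) {
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(df))
        stop("mapped column not found in file: ", col_map[[canon]])
      names(df)[names(df) == col_map[[canon]]] <- canon
    }
  }
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read a spot intensity table
#'
#' Reads per-individual 2D-DIGE spot intensities (arbitrary fluorescence
#' units). Each individual must carry a reading for every reference spot;
#' target spots missing from the file are imputed as intensity 0 (absent)
#' with a warning, unless `strict = TRUE`.
#'
#' @param path Path to a TSV/CSV file with columns `individual`, `spot`,
#'   `intensity`.
#' @param universe A [spot_universe()].
#' @param dialect `"tsv"` or `"csv"`.
#' @param strict If `TRUE`, a missing target spot is an error instead of an
#'   imputed zero.
#' @param col_map Optional column-name mapping, as in [read_po_table()].
#' @return A data.frame of class `spot_intensity_table`.
#' @export
read_spot_table <- function(path, universe = spot_universe(),
                            dialect = c("tsv", "csv"), strict = FALSE,
                            col_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  df <- remap_columns(df, col_map, c("individual", "spot", "intensity"))
  spot_intensity_table(df[c("individual", "spot", "intensity")],
                       universe, strict = strict)
}

#' Validate a spot intensity table
#'
#' @param df Data.frame with columns `individual`, `spot`, `intensity`.
#' @inheritParams read_spot_table
#' @return A data.frame of class `spot_intensity_table` with attribute
#'   `universe`.
#' @export
spot_intensity_table <- function(df, universe = spot_universe(),
                                 strict = FALSE) {
  df$individual <- as.character(df$individual)
  df$spot <- as.character(df$spot)
  df$intensity <- as.numeric(df$intensity)
  valid <- c(as.character(universe$spot_ids), universe$reference_ids)
  bad <- which(!df$spot %in% valid)
  if (length(bad))
    stop("unknown spot label in row(s): ", paste(bad, collapse = ", "))
  bad <- which(is.na(df$intensity) | df$intensity < 0)
  if (length(bad))
    stop("negative or missing intensity in row(s): ",
         paste(bad, collapse = ", "))
  key <- paste(df$individual, df$spot, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (individual, spot) in row(s): ",
         paste(dup, collapse = ", "))

  inds <- unique(df$individual)
  for (ind in inds) {
    have <- df$spot[df$individual == ind]
    miss_ref <- setdiff(universe$reference_ids, have)
    if (length(miss_ref))
      stop("individual ", ind, " is missing reference spot(s): ",
           paste(miss_ref, collapse = ", "))
    miss_tgt <- setdiff(as.character(universe$spot_ids), have)
    if (length(miss_tgt)) {
      if (strict)
        stop("individual ", ind, " is missing target spot(s): ",
             paste(miss_tgt, collapse = ", "))
      warning("individual ", ind, ": target spot(s) ",
              paste(miss_tgt, collapse = ", "),
              " absent from table; imputed as intensity 0", call. = FALSE)
      df <- rbind(df, data.frame(individual = ind, spot = miss_tgt,
                                 intensity = 0))
    }
  }
  rownames(df) <- NULL
  attr(df, "universe") <- universe
  class(df) <- c("spot_intensity_table", "data.frame")
  df
}

#' Write a spot intensity table
#' @param x A `spot_intensity_table`.
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @export
write_spot_table <- function(x, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  utils::write.table(as.data.frame(x), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a CR matrix as a square TSV
#'
#' The on-disk form is a square tab-separated matrix with individual IDs
#' as both header and first column.
#'
#' @param path File path.
#' @return For `read_cr_matrix`, a [cr_matrix()].
#' @export
read_cr_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  cr_matrix(m, individuals = rownames(m))
}

#' @rdname read_cr_matrix
#' @param x A `cr_matrix`.
#' @export
write_cr_matrix <- function(x, path) {
  utils::write.table(unclass(x), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Read / write spot profiles as JSON
#'
#' Profiles are serialized as an object mapping individual ID to the
#' sorted list of present spot labels.
#'
#' @param path File path.
#' @param universe A [spot_universe()].
#' @return For `read_profiles_json`, a [spot_profile_set()].
#' @export
read_profiles_json <- function(path, universe = spot_universe()) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  profs <- lapply(raw, function(v) as.integer(v))
  spot_profile_set(profs, universe)
}

#' @rdname read_profiles_json
#' @param x A `spot_profile_set`.
#' @export
write_profiles_json <- function(x, path) {
  jsonlite::write_json(lapply(unclass(x), function(v) sort(v)), path,
                       auto_unbox = FALSE)
  invisible(path)
}
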