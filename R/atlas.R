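#' @importFrom stats cor sd var optimize rnorm runif pt setNames
#' @importFrom utils read.csv write.csv head
NULL

# Functional-network labels recognised out of the box. "UNK" is a valid
# explicit label; user atlases may introduce additional labels freely.
.known_networks <- c("DMN", "VIS", "SM Hand", "SM Mouth", "CNG", "FRNT",
                     "SAL", "SUB", "CB", "AUD", "MEM", "VATT", "DATT", "UNK")

#' Read an ROI atlas table
#'
#' An atlas assigns every region of interest (ROI) an id, an MNI centroid in
#' millimetres and a functional-network label (e.g. DMN, VIS, SAL). ROI ids
#' must be unique and contiguous from 1; rows are returned in ascending id
#' order, which fixes the column order of every time-series matrix and
#' connectivity matrix downstream.
#'
#' @param path CSV/TSV file with header columns
#'   `roi_id,x,y,z,network[,anatomical_name]`.
#' @return An object of class `mgin_atlas`: a data.frame with columns
#'   `roi_id`, `x`, `y`, `z`, `network`, `anatomical_name` plus attribute
#'   `n_roi`.
#' @export
load_atlas <- function(path) {
  if (!file.exists(path)) stop("atlas file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        check.names = FALSE)
  req <- c("roi_id", "x", "y", "z", "network")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("atlas format error: missing column(s) ", paste(miss, collapse = ", "))
  if (!"anatomical_name" %in% names(df)) df$anatomical_name <- NA_character_
  validate_atlas(df[, c(req, "anatomical_name")])
}

#' Construct and validate an atlas from a data.frame
#'
#' @param df data.frame with columns roi_id, x, y, z, network and optionally
#'   anatomical_name.
#' @return Validated `mgin_atlas`.
#' @export
validate_atlas <- function(df) {
  if (!"anatomical_name" %in% names(df)) df$anatomical_name <- NA_character_
  df$roi_id <- as.integer(df$roi_id)
  if (anyNA(df$roi_id)) stop("atlas format error: non-integer roi_id")
  if (anyDuplicated(df$roi_id))
    stop("atlas format error: duplicate roi_id ",
         paste(unique(df$roi_id[duplicated(df$roi_id)]), collapse = ", "))
  df <- df[order(df$roi_id), , drop = FALSE]
  n <- nrow(df)
  if (n < 2) stop("atlas format error: need at least 2 ROIs")
  if (!identical(df$roi_id, seq_len(n)))
    stop("atlas format error: roi_id must be contiguous 1..N")
  df$network <- as.character(df$network)
  if (any(is.na(df$network) | !nzchar(df$network)))
    stop("atlas format error: missing network label")
  for (col in c("x", "y", "z")) {
    df[[col]] <- as.numeric(df[[col]])
    if (any(!is.finite(df[[col]])))
      stop("atlas format error: non-finite coordinate in column ", col)
  }
  rownames(df) <- NULL
  structure(df, n_roi = n, class = c("mgin_atlas", "data.frame"))
}

#' Write an atlas back to CSV
#'
#' @param atlas an `mgin_atlas`.
#' @param path output CSV path.
#' @export
write_atlas <- function(atlas, path) {
  utils::write.csv(as.data.frame(atlas), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Number of ROIs in an atlas
#' @param atlas an `mgin_atlas`.
#' @export
n_roi <- function(atlas) attr(atlas, "n_roi")

#' Path to the bundled 264-ROI fixture atlas
#'
#' A synthetic stand-in for a 264-region functional parcellation: network
#' label frequencies follow the usual proportions of such templates
#' (DMN 58, VIS 31, SM Hand 30, FRNT 25, SAL 18, CNG 14, SUB 13, SM Mouth 5,
#' CB 4, UNK 66) but coordinates and anatomical names are synthetic. Useful
#' for tests and demonstrations; not a real brain template.
#'
#' @return File path of the bundled CSV.
#' @export
fixture_atlas_path <- function() {
  system.file("extdata", "atlas264_synthetic.csv", package = "mginconn",
              mustWork = TRUE)
}

#' Read subject metadata
#'
#' @param path CSV with header `subject_id,sex,age`.
#' @return data.frame with character `subject_id`, integer `sex` in {0,1}
#'   and numeric `age` (years).
#' @export
load_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "sex", "age")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("metadata format error: missing column(s) ", paste(miss, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) stop("metadata format error: duplicate subject_id")
  df$sex <- as.integer(df$sex)
  if (any(!df$sex %in% c(0L, 1L))) stop("metadata format error: sex must be 0/1")
  df$age <- as.numeric(df$age)
  if (any(!is.finite(df$age)) || any(df$age < 0))
    stop("metadata format error: age must be a non-negative number")
  df
}

#' Write subject metadata
#' @param meta data.frame with subject_id, sex, age.
#' @param path output CSV path.
#' @export
write_metadata <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Adolescence stage of an age in years
#'
#' Five developmental stages partition the 8-22 year span: Pre 8-12,
#' Early 12-14, Middle 14-16, Late 16-18, Post 18-22. Published stage tables
#' share their endpoints, so intervals are taken half-open on the right with
#' the final interval closed: [8,12), [12,14), [14,16), [16,18), [18,22].
#'
#' @param age numeric vector of ages in years, each in [8, 22].
#' @return character vector of stage labels among
#'   `c("Pre","Early","Middle","Late","Post")`.
#' @export
assign_stage <- function(age) {
  age <- as.numeric(age)
  if (any(!is.finite(age)) || any(age < 8 | age > 22))
    stop("age out of range: stages are defined on [8, 22]")
  cut_pts <- c(8, 12, 14, 16, 18, 22)
  lab <- stage_levels()
  idx <- findInterval(age, cut_pts, rightmost.closed = TRUE)
  lab[idx]
}

#' Stage labels in developmental order
#' @export
stage_levels <- function() c("Pre", "Early", "Middle", "Late", "Post")

#' Read an ROI time-series matrix
#'
#' One file per subject per paradigm: a delimited numeric matrix with rows =
#' timepoints and columns = ROIs in atlas order.
#'
#' @param path CSV/TSV numeric matrix (no header or a header of ROI ids).
#' @param atlas `mgin_atlas` fixing the expected column count.
#' @param subject_id,modality identifiers attached to the result.
#' @return An `mgin_timeseries`: numeric T x N matrix with attributes
#'   `subject_id` and `modality`.
#' @export
load_timeseries <- function(path, atlas, subject_id = NA_character_,
                            modality = NA_character_) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  m <- as.matrix(utils::read.csv(path, sep = sep, header = has_header))
  storage.mode(m) <- "double"
  validate_timeseries(m, atlas, subject_id, modality)
}

#' Validate a T x N time-series matrix against an atlas
#'
#' @param values numeric matrix, rows = timepoints, columns = ROIs.
#' @param atlas `mgin_atlas`.
#' @param subject_id,modality identifiers.
#' @return `mgin_timeseries` object.
#' @export
validate_timeseries <- function(values, atlas, subject_id = NA_character_,
                                modality = NA_character_) {
  values <- as.matrix(values)
  N <- n_roi(atlas)
  if (ncol(values) != N)
    stop(sprintf("dimension mismatch: time series has %d columns, atlas has %d ROIs",
                 ncol(values), N))
  if (nrow(values) < 3) stop("data error: need at least 3 timepoints")
  if (any(!is.finite(values))) stop("data error: non-finite values in time series")
  v <- apply(values, 2, stats::var)
  if (any(v <= 0)) {
    bad <- which(v <= 0)
    stop("data error: zero-variance time series for roi_id ",
         paste(bad, collapse = ", "))
  }
  dimnames(values) <- NULL
  structure(values, subject_id = as.character(subject_id),
            modality = as.character(modality),
            class = c("mgin_timeseries", "matrix", "array"))
}

#' Write a time-series matrix to CSV
#' @param ts `mgin_timeseries` or plain matrix.
#' @param path output CSV path.
#' @export
write_timeseries <- function(ts, path) {
  utils::write.table(unclass(ts), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a cohort of time series
#'
#' Two on-disk layouts produce identical cohorts: a directory of per-subject
#' CSVs named `<subject_id>_<modality>.csv`, or a single RDS container (a
#' named list keyed `subject_id/modality`) written by [save_cohort()].
#'
#' @param path directory or `.rds` container.
#' @param atlas `mgin_atlas`.
#' @param metadata data.frame from [load_metadata()].
#' @param modalities character vector of paradigm tags to load.
#' @return Named list `subject_id -> modality -> mgin_timeseries`.
#' @export
load_cohort <- function(path, atlas, metadata,
                        modalities = c("emoid", "nback")) {
  out <- list()
  if (dir.exists(path)) {
    for (sid in metadata$subject_id) {
      out[[sid]] <- list()
      for (mod in modalities) {
        f <- file.path(path, paste0(sid, "_", mod, ".csv"))
        if (!file.exists(f))
          stop("missing time series for subject ", sid, " modality ", mod)
        out[[sid]][[mod]] <- load_timeseries(f, atlas, sid, mod)
      }
    }
  } else if (grepl("\\.rds$", path, ignore.case = TRUE) && file.exists(path)) {
    container <- readRDS(path)
    for (sid in metadata$subject_id) {
      out[[sid]] <- list()
      for (mod in modalities) {
        key <- paste0(sid, "/", mod)
        if (is.null(container[[key]]))
          stop("container missing key ", key)
        out[[sid]][[mod]] <- validate_timeseries(container[[key]], atlas, sid, mod)
      }
    }
  } else stop("cohort path not found: ", path)
  out
}

#' Write a cohort either as per-subject CSVs or a single RDS container
#'
#' @param cohort nested list as returned by [load_cohort()].
#' @param path target directory (CSV layout) or `.rds` file (container).
#' @export
save_cohort <- function(cohort, path) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    container <- list()
    for (sid in names(cohort))
      for (mod in names(cohort[[sid]]))
        container[[paste0(sid, "/", mod)]] <- unclass(cohort[[sid]][[mod]])
    saveRDS(container, path)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (sid in names(cohort))
      for (mod in names(cohort[[sid]]))
        write_timeseries(cohort[[sid]][[mod]],
                         file.path(path, paste0(sid, "_", mod, ".csv")))
  }
  invisible(path)
}
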