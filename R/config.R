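#' Default pipeline configuration
#'
#' Parameter defaults follow the acquisition/processing protocol the pipeline
#' models: SHARP variable-kernel maximum radius 4 mm with regularization 0.05,
#' brain-mask fractional threshold 0.3, ROI erosion of 2 voxels, band-pass
#' 0.01-0.1 Hz, voxelwise mask FDR 0.001, tabular FDR 0.05, and LSQR with
#' tolerance 1e-6 and at most 300 iterations using the 2nd and 3rd echoes
#' (TE 12 and 18 ms).
#'
#' @return A `pipeline_config`: a named list of sections `qsm`,
#'   `connectivity`, `stats`, plus `seed`.
#' @export
default_config <- function() {
  cfg <- list(
    qsm = list(
      sharp_max_radius_mm = 4,
      sharp_regularization = 0.05,
      bet_fractional_threshold = 0.3,
      erosion_voxels = 2,
      echoes_used = c(2L, 3L),
      lsqr_tol = 1e-6,
      lsqr_maxit = 300L
    ),
    connectivity = list(
      band_low_hz = 0.01,
      band_high_hz = 0.1,
      fdr_threshold = 0.001
    ),
    stats = list(
      fdr_level = 0.05
    ),
    seed = 1L
  )
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  q <- cfg$qsm; cn <- cfg$connectivity
  if (q$sharp_max_radius_mm <= 0) stop("SHARP radius must be positive", call. = FALSE)
  if (q$sharp_regularization <= 0 || q$sharp_regularization >= 1) {
    stop("SHARP regularization must lie in (0, 1)", call. = FALSE)
  }
  if (q$erosion_voxels < 0) stop("erosion must be >= 0 voxels", call. = FALSE)
  if (!(cn$band_low_hz > 0) || !(cn$band_low_hz < cn$band_high_hz)) {
    stop("band-pass edges must satisfy 0 < low < high", call. = FALSE)
  }
  if (cn$fdr_threshold <= 0 || cn$fdr_threshold > 1) {
    stop("FDR threshold must lie in (0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

#' Load a pipeline configuration file
#'
#' Flat `key = value` text format with `[section]` headers (sections `qsm`,
#' `connectivity`, `stats`; `seed` at top level). Unknown keys are an error;
#' unspecified keys keep their defaults. Booleans are literal `true`/`false`;
#' vectors are comma-separated.
#'
#' @param path Path to the config file, or `NULL` for pure defaults.
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(validate_config(cfg))
  if (!file.exists(path)) stop(sprintf("config not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (!section %in% c("qsm", "connectivity", "stats")) {
        stop(sprintf("unknown config section '%s'", section), call. = FALSE)
      }
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop(sprintf("malformed config line: '%s'", ln), call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    parsed <- parse_config_value(val)
    if (is.null(section)) {
      if (key != "seed") stop(sprintf("unknown top-level key '%s'", key), call. = FALSE)
      cfg$seed <- as.integer(parsed)
    } else {
      if (!key %in% names(cfg[[section]])) {
        stop(sprintf("unknown key '%s' in section [%s]", key, section), call. = FALSE)
      }
      cfg[[section]][[key]] <- if (key == "echoes_used") as.integer(parsed) else parsed
    }
  }
  validate_config(cfg)
}

parse_config_value <- function(val) {
  if (tolower(val) %in% c("true", "false")) return(tolower(val) == "true")
  parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
  num <- suppressWarnings(as.numeric(parts))
  if (any(is.na(num))) return(parts)
  num
}

#' Read a subject metadata table
#'
#' TSV with header columns `subject_id`, `group`, `apoe_e4`, `age`, `gender`.
#' `group` (control/MCI) and `apoe_e4` (true/false or 0/1) are parsed
#' case-insensitively; duplicate subject ids are rejected.
#'
#' @param path Path to the TSV file.
#' @return A tibble, one row per subject, with columns `subject_id`
#'   (character), `group` (factor control/MCI), `apoe_e4` (logical), `age`
#'   (numeric years), `gender` (factor F/M).
#' @export
read_subject_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  # read as character: columns like an all-"F" gender would otherwise be
  # type-converted to logical
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("subject_id", "group", "apoe_e4", "age", "gender")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("subject table missing columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  as_subject_table(df)
}

#' Validate and normalize a subject data frame
#'
#' @param df Data frame with the subject-table columns.
#' @return A normalized tibble (see [read_subject_table()]).
#' @export
as_subject_table <- function(df) {
  grp <- tolower(trimws(as.character(df$group)))
  bad <- setdiff(unique(grp), c("control", "mci"))
  if (length(bad)) {
    stop(sprintf("unknown group value(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  ap <- tolower(trimws(as.character(df$apoe_e4)))
  apv <- ap %in% c("true", "1", "t", "yes")
  apf <- ap %in% c("false", "0", "f", "no")
  if (any(!(apv | apf))) {
    stop(sprintf("unparseable apoe_e4 value(s): %s",
                 paste(unique(ap[!(apv | apf)]), collapse = ", ")), call. = FALSE)
  }
  gen <- toupper(trimws(as.character(df$gender)))
  if (any(!gen %in% c("F", "M"))) {
    stop("gender must be F or M", call. = FALSE)
  }
  ids <- as.character(df$subject_id)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate subject_id: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")), call. = FALSE)
  }
  age <- as.numeric(df$age)
  if (any(!is.finite(age)) || any(age < 40) || any(age > 110)) {
    stop("age must lie in [40, 110] years", call. = FALSE)
  }
  tibble::tibble(
    subject_id = ids,
    group = factor(ifelse(grp == "mci", "MCI", "control"),
                   levels = c("control", "MCI")),
    apoe_e4 = apv,
    age = age,
    gender = factor(gen, levels = c("F", "M"))
  )
}

#' Write a subject table as TSV
#'
#' @param subjects Subject tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_subject_table <- function(subjects, path) {
  df <- as.data.frame(subjects)
  df$apoe_e4 <- tolower(as.character(df$apoe_e4))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a provenance record
#'
#' Every pipeline run records its resolved configuration, seed, package
#' version and the MD5 of each input file, so reruns can be verified
#' bit-identical. No timestamps are stored: the record itself must be
#' reproducible.
#'
#' @param path Output JSON path.
#' @param config Resolved `pipeline_config`.
#' @param seed Integer seed used for the run.
#' @param inputs Character vector of input file paths (hashed if they exist).
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, config, seed, inputs = character()) {
  hashes <- vapply(inputs, function(f) {
    if (file.exists(f)) unname(digest::digest(f, algo = "md5", file = TRUE)) else NA_character_
  }, character(1))
  rec <- list(
    package = "qsmcoloc",
    version = as.character(utils::packageVersion("qsmcoloc")),
    seed = seed,
    config = unclass(config),
    inputs = as.list(hashes)
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
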