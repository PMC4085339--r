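# Peak-list file formats and run configuration.
#
# MGF subset: BEGIN IONS / END IONS blocks with TITLE (sample id), PEPMASS
# (precursor m/z; first number on the line) and whitespace-separated
# "m/z intensity" peak lines. TSV: two numeric columns m/z and intensity,
# '#'-prefixed comments, with an optional "# precursor=<mz>" header.

#' Read a peak list from MGF or TSV
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"mgf"` or `"tsv"`.
#' @return A [peaklist()]; peaks are sorted ascending on load. For MGF
#'   files with several blocks, a list of peaklists is returned.
#' @export
read_peaklist <- function(path, format = c("auto", "mgf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.mgf$", path, ignore.case = TRUE)) "mgf" else "tsv"
  }
  lines <- readLines(path, warn = FALSE)
  if (length(trimws(lines)[nzchar(trimws(lines))]) == 0) {
    stop("empty peak-list file: ", path, call. = FALSE)
  }
  if (format == "mgf") .read_mgf(lines, path) else .read_tsv(lines, path)
}

.read_mgf <- function(lines, path) {
  out <- list()
  in_block <- FALSE
  mz <- numeric(0); int <- numeric(0)
  title <- ""; pepmass <- NULL
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (line == "BEGIN IONS") {
      if (in_block) stop("nested BEGIN IONS at line ", i, call. = FALSE)
      in_block <- TRUE
      mz <- numeric(0); int <- numeric(0); title <- ""; pepmass <- NULL
    } else if (line == "END IONS") {
      if (!in_block) stop("END IONS without BEGIN IONS at line ", i,
                          call. = FALSE)
      out[[length(out) + 1L]] <- peaklist(mz, int, precursor_mz = pepmass,
                                          sample_id = title)
      in_block <- FALSE
    } else if (!in_block) {
      stop("content outside BEGIN IONS/END IONS at line ", i, call. = FALSE)
    } else if (grepl("^TITLE=", line)) {
      title <- sub("^TITLE=", "", line)
    } else if (grepl("^PEPMASS=", line)) {
      v <- suppressWarnings(as.numeric(
        strsplit(sub("^PEPMASS=", "", line), "\\s+")[[1]][1]))
      if (is.na(v)) stop("malformed PEPMASS at line ", i, call. = FALSE)
      pepmass <- v
    } else if (grepl("^[A-Z]+=", line)) {
      next  # other headers tolerated
    } else {
      fields <- suppressWarnings(as.numeric(strsplit(line,
                                                     "[[:space:]]+")[[1]]))
      if (length(fields) < 1 || anyNA(fields[1])) {
        stop("malformed peak line ", i, " in ", path, call. = FALSE)
      }
      mz <- c(mz, fields[1])
      int <- c(int, if (length(fields) >= 2 && !is.na(fields[2]))
        fields[2] else 1)
    }
  }
  if (in_block) stop("unterminated BEGIN IONS block in ", path,
                     call. = FALSE)
  if (length(out) == 0) stop("no spectra in ", path, call. = FALSE)
  if (length(out) == 1L) out[[1]] else out
}

.read_tsv <- function(lines, path) {
  pepmass <- NULL
  m <- regmatches(lines, regexec("^#\\s*precursor\\s*=\\s*([0-9.eE+-]+)",
                                 lines))
  hit <- which(lengths(m) > 0)
  if (length(hit) > 0) pepmass <- as.numeric(m[[hit[1]]][2])
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0) stop("no peaks in ", path, call. = FALSE)
  mz <- numeric(length(body)); int <- numeric(length(body))
  for (i in seq_along(body)) {
    fields <- suppressWarnings(as.numeric(strsplit(trimws(body[i]),
                                                   "[[:space:],]+")[[1]]))
    if (length(fields) < 1 || anyNA(fields[1])) {
      stop("malformed peak line: ", sQuote(body[i]), " in ", path,
           call. = FALSE)
    }
    mz[i] <- fields[1]
    int[i] <- if (length(fields) >= 2 && !is.na(fields[2])) fields[2] else 1
  }
  peaklist(mz, int, precursor_mz = pepmass,
           sample_id = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a peak list to MGF or TSV
#'
#' @param pl a [peaklist()].
#' @param path output path.
#' @param format `"mgf"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(pl, path, format = c("mgf", "tsv")) {
  stopifnot(inherits(pl, "peaklist"))
  format <- match.arg(format)
  if (format == "mgf") {
    lines <- c("BEGIN IONS",
               paste0("TITLE=", pl$sample_id),
               if (!is.null(pl$precursor_mz))
                 sprintf("PEPMASS=%.6f", pl$precursor_mz),
               sprintf("%.6f %.6f", pl$peaks$mz, pl$peaks$intensity),
               "END IONS")
  } else {
    lines <- c(if (!is.null(pl$precursor_mz))
      sprintf("# precursor=%.6f", pl$precursor_mz),
      sprintf("%.6f\t%.6f", pl$peaks$mz, pl$peaks$intensity))
  }
  writeLines(lines, path)
  invisible(path)
}

.RUN_CONFIG_KEYS <- c("backbone_lengths", "acyl_carbons", "max_double_bonds",
                      "max_hydroxyls", "allow_carbamoyl", "allow_o_acetyl",
                      "allow_methyl", "tolerance_da", "nominal_mode",
                      "adducts", "min_fragment_matches", "mz_jitter_sd",
                      "n_decoys", "seed", "input", "output", "verbosity")

#' Read a run configuration from YAML
#'
#' Known keys cover the search-space bounds, matching parameters,
#' simulation noise settings, paths and verbosity; unknown keys are
#' rejected. Values round-trip losslessly through [write_run_config()].
#'
#' @param path YAML file path.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), .RUN_CONFIG_KEYS)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @param cfg a `run_config` (or plain named list with known keys).
#' @export
write_run_config <- function(cfg, path) {
  unknown <- setdiff(names(cfg), .RUN_CONFIG_KEYS)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Serialize an annotation result to JSON
#'
#' @param result an `annotation_result`.
#' @param path optional output file; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
annotation_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "annotation_result"))
  obj <- list(precursor_mz = result$precursor_mz,
              ambiguity_flag = result$ambiguity_flag,
              candidates = result$candidates,
              unmatched_peaks = result$unmatched_peaks,
              tool = paste0("lcoms ",
                            as.character(utils::packageVersion("lcoms"))))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Serialize a differential report to JSON
#'
#' @param report a `differential_report`.
#' @param path optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
differential_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "differential_report"))
  obj <- unclass(report)
  obj$tool <- paste0("lcoms ",
                     as.character(utils::packageVersion("lcoms")))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
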