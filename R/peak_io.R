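# Readers/writers for the tabular formats the pipeline touches. Everything is
# plain UTF-8 CSV/TSV; the field separator is auto-detected from the header
# line (tab if present, comma otherwise). Readers validate into domain types
# and never silently drop rows: malformed rows raise errors that name them.

DIGESTS <- c("HPA", "MSP")
STATES <- c("NMT", "HMM", "ICM", "HPM")
SITES <- c("TG", "PM", "AH", "PS")
SEASONS <- c("DRY", "WET")
STATUSES <- c("BT", "DA", "AA", "TGC", "PSC", "NONE")

# Column-name dialect: genotyping exports differ, so the mapping from our
# canonical names to file headers is configurable.
default_dialect <- function() {
  list(sample = "Sample", digest = "Digest", size = "Size",
       height = "Height", dye = "Dye")
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  utils::read.table(path, header = TRUE, sep = detect_sep(path),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", quote = "\"", fileEncoding = "UTF-8")
}

normalize_digest <- function(x) {
  up <- toupper(trimws(x))
  out <- rep(NA_character_, length(up))
  out[up %in% c("HPA", "HPAII", "H")] <- "HPA"
  out[up %in% c("MSP", "MSPI", "M")] <- "MSP"
  out
}

#' Read a capillary-electrophoresis peak table
#'
#' Reads an exported peak table (one row per called peak) and validates it
#' into a `peak_table`: sample identifier, digest enzyme (HpaII or MspI),
#' fragment size in bp and signal intensity in relative fluorescence units
#' (RFU). Digest labels are matched case-insensitively against
#' HPA/HPAII and MSP/MSPI.
#'
#' @param path path to a CSV or TSV file.
#' @param dialect named list mapping canonical fields (`sample`, `digest`,
#'   `size`, `height`, optional `dye`) to the file's column names; defaults
#'   to `Sample`, `Digest`, `Size`, `Height`, `Dye`.
#' @param digest if the file holds a single digest and has no digest column,
#'   give it here (`"HPA"` or `"MSP"`); the two per-digest files can then be
#'   combined with `rbind`.
#' @return a `peak_table` data frame with columns `sample_id`, `digest`,
#'   `size`, `height` (and `dye` when present). The number of accepted rows
#'   is reported via `message()`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(Sample = "S01", Digest = "HPA",
#'                      Size = 120.3, Height = 55), f, row.names = FALSE)
#' read_peak_table(f)
#' @export
read_peak_table <- function(path, dialect = default_dialect(), digest = NULL) {
  dl <- utils::modifyList(default_dialect(), as.list(dialect))
  raw <- read_delim_auto(path)
  need <- c("sample", "size", "height")
  if (is.null(digest)) need <- c(need, "digest")
  for (fld in need) {
    if (!dl[[fld]] %in% names(raw))
      stopf("peak table '%s' is missing required column '%s' (field '%s')",
            path, dl[[fld]], fld)
  }
  n_in <- nrow(raw)
  size <- suppressWarnings(as.numeric(raw[[dl$size]]))
  height <- suppressWarnings(as.numeric(raw[[dl$height]]))
  bad <- which(is.na(size) & !is.na(raw[[dl$size]]) |
               is.na(height) & !is.na(raw[[dl$height]]))
  if (length(bad))
    stopf("non-numeric size/height in rows: %s",
          paste(utils::head(bad, 10L), collapse = ", "))
  if (is.null(digest)) {
    dig <- normalize_digest(raw[[dl$digest]])
    if (anyNA(dig))
      stopf("unknown digest value(s): %s",
            paste(unique(raw[[dl$digest]][is.na(dig)]), collapse = ", "))
  } else {
    digest <- match.arg(toupper(digest), DIGESTS)
    dig <- rep(digest, n_in)
  }
  if (any(!is.na(size) & size <= 0))
    stopf("fragment size must be > 0 (rows: %s)",
          paste(utils::head(which(size <= 0), 10L), collapse = ", "))
  if (any(!is.na(height) & height < 0))
    stopf("peak height must be >= 0 (rows: %s)",
          paste(utils::head(which(height < 0), 10L), collapse = ", "))
  if (anyNA(size) || anyNA(height))
    stopf("missing size/height in rows: %s",
          paste(utils::head(which(is.na(size) | is.na(height)), 10L),
                collapse = ", "))
  out <- data.frame(sample_id = as.character(raw[[dl$sample]]),
                    digest = dig, size = size, height = height,
                    stringsAsFactors = FALSE)
  if (dl$dye %in% names(raw)) out$dye <- as.character(raw[[dl$dye]])
  class(out) <- c("peak_table", "data.frame")
  message(sprintf("read_peak_table: accepted %d of %d rows", nrow(out), n_in))
  out
}

#' Write a peak table
#'
#' @param pt a `peak_table` (see [read_peak_table()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(pt, path) {
  stopifnot(inherits(pt, "peak_table") || is.data.frame(pt))
  df <- as.data.frame(pt)
  names(df)[match(c("sample_id", "digest", "size", "height"), names(df))] <-
    c("Sample", "Digest", "Size", "Height")
  if ("dye" %in% names(df)) names(df)[names(df) == "dye"] <- "Dye"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a two-digest fragment presence/absence matrix
#'
#' An MSAP fragment matrix holds, for each sample and fragment-size locus,
#' presence (1) / absence (0) / unscored (NA) in each of the two isoschizomer
#' digests (HpaII, MspI). NA is kept distinct from 0 because joint absence
#' (0/0) is analytically meaningful (hypermethylation).
#'
#' @param hpa,msp numeric matrices (samples x loci) with values in
#'   \{0, 1, NA\}, identical dimnames.
#' @return a `fragment_matrix` object.
#' @export
fragment_matrix <- function(hpa, msp) {
  hpa <- as.matrix(hpa); msp <- as.matrix(msp)
  if (!identical(dim(hpa), dim(msp)))
    stopf("HPA and MSP layers differ in dimension")
  if ((nrow(hpa) > 0L && is.null(rownames(hpa))) ||
      (ncol(hpa) > 0L && is.null(colnames(hpa))))
    stopf("fragment matrices need sample rownames and locus colnames")
  if (!identical(dimnames(hpa), dimnames(msp)))
    stopf("HPA and MSP layers differ in sample/locus names")
  if (anyDuplicated(rownames(hpa))) stopf("duplicated sample_id")
  if (anyDuplicated(colnames(hpa))) stopf("duplicated locus id")
  if (!is_binary(hpa) || !is_binary(msp))
    stopf("fragment matrix cells must be 0, 1 or NA")
  structure(list(hpa = hpa, msp = msp,
                 samples = rownames(hpa) %||% character(0),
                 loci = colnames(hpa) %||% character(0)),
            class = "fragment_matrix")
}

#' @export
print.fragment_matrix <- function(x, ...) {
  cat(sprintf("MSAP fragment matrix: %d samples x %d loci x 2 digests (HpaII/MspI)\n",
              length(x$samples), length(x$loci)))
  pres <- mean(x$hpa == 1, na.rm = TRUE) + mean(x$msp == 1, na.rm = TRUE)
  cat(sprintf("  mean fragment presence: %.1f%%\n", 50 * pres))
  invisible(x)
}

#' @export
dim.fragment_matrix <- function(x) c(length(x$samples), length(x$loci))

#' Read a pre-binarized fragment matrix
#'
#' Reads the canonical CSV layout written by [write_fragment_matrix()]:
#' a `sample_id` column followed by one column per locus and digest, named
#' `<locus>.HPA` and `<locus>.MSP`, cells in \{0, 1, NA\}.
#'
#' @param path CSV/TSV path.
#' @return a `fragment_matrix`.
#' @export
read_fragment_matrix <- function(path) {
  raw <- read_delim_auto(path)
  if (!"sample_id" %in% names(raw)) stopf("missing 'sample_id' column")
  ids <- as.character(raw$sample_id)
  if (anyDuplicated(ids))
    stopf("duplicated sample_id: %s", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cols <- setdiff(names(raw), "sample_id")
  is_hpa <- grepl("\\.HPA$", cols)
  is_msp <- grepl("\\.MSP$", cols)
  if (!all(is_hpa | is_msp))
    stopf("locus columns must end in .HPA or .MSP (offending: %s)",
          paste(utils::head(cols[!(is_hpa | is_msp)], 5L), collapse = ", "))
  loci_h <- sub("\\.HPA$", "", cols[is_hpa])
  loci_m <- sub("\\.MSP$", "", cols[is_msp])
  if (!setequal(loci_h, loci_m))
    stopf("HPA and MSP locus sets differ")
  loci <- sort(loci_h)
  take <- function(suffix) {
    m <- as.matrix(raw[paste0(loci, suffix)])
    mode(m) <- "numeric"
    dimnames(m) <- list(ids, loci)
    m
  }
  # coercion of junk like "2" stays "2" numerically -- catch out-of-range
  hpa <- take(".HPA"); msp <- take(".MSP")
  bad <- c(hpa[!(hpa %in% c(0, 1) | is.na(hpa))],
           msp[!(msp %in% c(0, 1) | is.na(msp))])
  if (length(bad))
    stopf("fragment matrix cells must be 0, 1 or NA (found: %s)",
          paste(unique(utils::head(bad, 5L)), collapse = ", "))
  fragment_matrix(hpa, msp)
}

#' Write a fragment matrix
#'
#' @param fm a `fragment_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fragment_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "fragment_matrix"))
  df <- data.frame(sample_id = fm$samples, stringsAsFactors = FALSE)
  for (l in fm$loci) {
    df[[paste0(l, ".HPA")]] <- fm$hpa[, l]
    df[[paste0(l, ".MSP")]] <- fm$msp[, l]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read sample metadata
#'
#' Expects columns `sample_id`, `site` and either `season` or `timepoint`
#' (season is then derived with [season_of()]); optional `status` for
#' transplant-experiment samples (BT pre-transplant, DA during
#' acclimatization, AA post-acclimatization, TGC/PSC caged controls).
#'
#' @param path CSV/TSV path.
#' @return a data frame with factor columns `site`, `season`, `status`.
#' @export
read_sample_metadata <- function(path) {
  raw <- read_delim_auto(path)
  if (!"sample_id" %in% names(raw)) stopf("missing 'sample_id' column")
  ids <- as.character(raw$sample_id)
  if (anyDuplicated(ids))
    stopf("duplicated sample_id in metadata: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!"site" %in% names(raw)) stopf("missing 'site' column")
  site <- toupper(trimws(raw$site))
  if (!all(site %in% SITES))
    stopf("unknown site(s): %s", paste(setdiff(unique(site), SITES), collapse = ", "))
  if ("season" %in% names(raw)) {
    season <- toupper(trimws(raw$season))
    if (!all(season %in% SEASONS))
      stopf("unknown season(s): %s", paste(setdiff(unique(season), SEASONS), collapse = ", "))
  } else if ("timepoint" %in% names(raw)) {
    season <- vapply(as.Date(raw$timepoint), season_of, character(1))
  } else stopf("metadata needs a 'season' or 'timepoint' column")
  status <- if ("status" %in% names(raw)) toupper(trimws(raw$status)) else
    rep("NONE", nrow(raw))
  status[is.na(status) | status == ""] <- "NONE"
  if (!all(status %in% STATUSES))
    stopf("unknown status value(s): %s",
          paste(setdiff(unique(status), STATUSES), collapse = ", "))
  out <- data.frame(sample_id = ids,
                    site = factor(site, levels = SITES),
                    season = factor(season, levels = SEASONS),
                    status = factor(status, levels = STATUSES),
                    stringsAsFactors = FALSE)
  if ("timepoint" %in% names(raw)) out$timepoint <- as.Date(raw$timepoint)
  out
}

#' Read a phenotype table
#'
#' One row per sample: `righting_time` in seconds (mean of up to three
#' trials) and `test_diameter` in mm, both strictly positive.
#'
#' @param path CSV/TSV path.
#' @return a validated data frame.
#' @export
read_phenotype_table <- function(path) {
  raw <- read_delim_auto(path)
  for (col in c("sample_id", "righting_time", "test_diameter"))
    if (!col %in% names(raw)) stopf("missing '%s' column", col)
  ids <- as.character(raw$sample_id)
  if (anyDuplicated(ids)) stopf("duplicated sample_id in phenotype table")
  rt <- as.numeric(raw$righting_time)
  td <- as.numeric(raw$test_diameter)
  if (any(!is.na(rt) & rt <= 0)) stopf("righting_time must be > 0")
  if (any(!is.na(td) & td <= 0)) stopf("test_diameter must be > 0")
  data.frame(sample_id = ids, righting_time = rt, test_diameter = td,
             stringsAsFactors = FALSE)
}
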