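#' Construct a scan set
#'
#' A `scan_set` holds time-ordered centroided mass spectra: a scan table
#' (index and retention time) and a centroid table (one row per centroid).
#' Scans may be empty (no centroids). Retention times must be strictly
#' increasing; centroids within a scan are kept sorted by m/z.
#'
#' @param scans Tibble/data frame with columns `scan` (integer index) and
#'   `rt_min` (retention time, minutes).
#' @param centroids Tibble/data frame with columns `scan`, `mz` (Da),
#'   `intensity` (counts). May have zero rows.
#' @param polarity `"+"` or `"-"` (metadata only).
#' @param mass_range Length-2 numeric acquisition range in Da.
#' @return A `scan_set` object.
#' @export
scan_set <- function(scans, centroids,
                     polarity = "+", mass_range = c(100, 2000)) {
  scans <- tibble::as_tibble(scans)[, c("scan", "rt_min")]
  centroids <- tibble::as_tibble(centroids)[, c("scan", "mz", "intensity")]
  stopifnot(nrow(scans) > 0, !anyNA(scans$rt_min))
  if (is.unsorted(scans$rt_min, strictly = TRUE)) {
    warning("scan retention times not strictly increasing; sorting",
            call. = FALSE)
    scans <- scans[order(scans$rt_min), ]
  }
  if (anyDuplicated(scans$scan) > 0) {
    stop("duplicate scan indices", call. = FALSE)
  }
  if (nrow(centroids) > 0) {
    if (!all(centroids$scan %in% scans$scan)) {
      stop("centroid rows reference unknown scan indices", call. = FALSE)
    }
    centroids <- dplyr::arrange(centroids, .data$scan, .data$mz)
  }
  structure(
    list(scans = scans, centroids = centroids,
         metadata = list(polarity = polarity, mass_range = mass_range)),
    class = "scan_set"
  )
}

#' @export
print.scan_set <- function(x, ...) {
  cat(sprintf(
    "<scan_set> %d scans, %d centroids, rt %.2f-%.2f min, polarity %s\n",
    nrow(x$scans), nrow(x$centroids),
    min(x$scans$rt_min), max(x$scans$rt_min), x$metadata$polarity
  ))
  invisible(x)
}

#' Number of scans in a scan set
#' @param scans A `scan_set`.
#' @return Integer scan count.
#' @export
n_scans <- function(scans) nrow(scans$scans)

#' Read centroided scan data
#'
#' Two formats are supported. `"internal_csv"` is the package's plain-text
#' scan format: comment lines `# polarity=` and `# mass_range=` followed by
#' a header `scan,rt_min,mz,intensity` and one row per centroid; an empty
#' scan is recorded as a row with empty `mz` and `intensity` fields.
#' `"mzml"` reads centroided spectra through the Bioconductor mzR package
#' (profile-mode spectra are rejected).
#'
#' @param path File to read.
#' @param format `"internal_csv"` or `"mzml"`.
#' @return A [scan_set()].
#' @export
read_scans <- function(path, format = c("internal_csv", "mzml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "internal_csv") read_scans_csv(path) else read_scans_mzml(path)
}

read_scans_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty scan file: ", path, call. = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  polarity <- sub("^# polarity=", "", grep("^# polarity=", meta_lines,
                                           value = TRUE))
  mass_range <- grep("^# mass_range=", meta_lines, value = TRUE)
  mass_range <- if (length(mass_range) == 1) {
    as.numeric(strsplit(sub("^# mass_range=", "", mass_range), ",")[[1]])
  } else {
    c(100, 2000)
  }
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 2) stop("no data rows in scan file: ", path,
                             call. = FALSE)
  if (body[1] != "scan,rt_min,mz,intensity") {
    stop("unexpected header in scan file (line ",
         which(!grepl("^#", lines))[1], "): ", body[1], call. = FALSE)
  }
  rows <- strsplit(body[-1], ",", fixed = TRUE)
  nf <- lengths(rows)
  bad <- which(nf != 4)
  if (length(bad) > 0) {
    # strsplit drops a trailing empty field; rows with empty mz+intensity
    # parse to length 3 ("12,0.50,,") or 2 ("12,0.50,,")
    fixable <- nf[bad] %in% c(2L, 3L)
    if (!all(fixable)) {
      stop("malformed row at line ", bad[!fixable][1] + 1L +
             sum(grepl("^#", lines)), call. = FALSE)
    }
    rows[bad] <- lapply(rows[bad], function(r) c(r, rep("", 4 - length(r))))
  }
  mat <- do.call(rbind, rows)
  suppressWarnings({
    scan_i <- as.integer(mat[, 1])
    rt <- as.numeric(mat[, 2])
    mz <- as.numeric(mat[, 3])
    intensity <- as.numeric(mat[, 4])
  })
  bad <- which(is.na(scan_i) | is.na(rt))
  if (length(bad) > 0) {
    stop("malformed row at line ",
         bad[1] + 1L + sum(grepl("^#", lines)), call. = FALSE)
  }
  scans <- tibble::tibble(scan = scan_i, rt_min = rt)
  scans <- dplyr::distinct(scans)
  keep <- !(is.na(mz) & mat[, 3] == "") # empty-field rows mark empty scans
  centroids <- tibble::tibble(scan = scan_i, mz = mz,
                              intensity = intensity)[keep, ]
  if (anyNA(centroids$mz) || anyNA(centroids$intensity)) {
    stop("malformed centroid values in ", path, call. = FALSE)
  }
  scan_set(scans, centroids,
           polarity = if (length(polarity) == 1) polarity else "+",
           mass_range = mass_range)
}

read_scans_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("mzML support requires the mzR package", call. = FALSE)
  }
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  if (nrow(hdr) == 0) stop("empty mzML file: ", path, call. = FALSE)
  if (any(hdr$centroided == 0 | is.na(hdr$centroided))) {
    stop("profile-mode spectra are not supported; centroid first",
         call. = FALSE)
  }
  peaks <- mzR::peaks(handle)
  if (is.matrix(peaks)) peaks <- list(peaks)
  centroids <- purrr::map_dfr(seq_along(peaks), function(i) {
    p <- peaks[[i]]
    if (nrow(p) == 0) return(NULL)
    tibble::tibble(scan = i, mz = p[, 1], intensity = p[, 2])
  })
  scans <- tibble::tibble(scan = seq_along(peaks),
                          rt_min = hdr$retentionTime / 60)
  pol <- if (all(hdr$polarity == 1)) "+" else "-"
  scan_set(scans, centroids, polarity = pol,
           mass_range = c(min(hdr$lowMZ), max(hdr$highMZ)))
}

#' Write centroided scan data
#'
#' Writes the internal scan CSV (m/z to 1e-4 Da, intensity to 1e-2 counts;
#' output is byte-stable for identical input) or an mzML file via mzR.
#'
#' @param scans A [scan_set()].
#' @param path Output file.
#' @param format `"internal_csv"` or `"mzml"`.
#' @return `path`, invisibly.
#' @export
write_scans <- function(scans, path, format = c("internal_csv", "mzml")) {
  format <- match.arg(format)
  stopifnot(inherits(scans, "scan_set"))
  if (format == "internal_csv") {
    write_scans_csv(scans, path)
  } else {
    write_scans_mzml(scans, path)
  }
  invisible(path)
}

write_scans_csv <- function(scans, path) {
  cen <- scans$centroids
  sc <- scans$scans
  empty <- sc[!(sc$scan %in% cen$scan), ]
  rows <- c(
    sprintf("%d,%.6f,%.4f,%.2f",
            cen$scan, sc$rt_min[match(cen$scan, sc$scan)],
            cen$mz, cen$intensity),
    sprintf("%d,%.6f,,", empty$scan, empty$rt_min)
  )
  ord <- order(c(cen$scan, empty$scan),
               c(cen$mz, rep(-Inf, nrow(empty))))
  con <- file(path, open = "wb") # fixed newline across platforms
  on.exit(close(con))
  writeLines(c(
    sprintf("# polarity=%s", scans$metadata$polarity),
    sprintf("# mass_range=%s",
            paste(format(scans$metadata$mass_range), collapse = ",")),
    "scan,rt_min,mz,intensity",
    rows[ord]
  ), con = con, sep = "\n")
}

write_scans_mzml <- function(scans, path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("mzML support requires the mzR package", call. = FALSE)
  }
  sc <- scans$scans
  cen <- scans$centroids
  pk <- lapply(sc$scan, function(i) {
    p <- cen[cen$scan == i, ]
    cbind(mz = p$mz, intensity = p$intensity)
  })
  npk <- vapply(pk, nrow, integer(1))
  hdr <- data.frame(
    seqNum = seq_len(nrow(sc)), acquisitionNum = seq_len(nrow(sc)),
    msLevel = 1L, polarity = if (scans$metadata$polarity == "+") 1L else 0L,
    peaksCount = npk, totIonCurrent = vapply(
      pk, function(p) sum(p[, 2]), numeric(1)),
    retentionTime = sc$rt_min * 60,
    basePeakMZ = vapply(pk, function(p) if (nrow(p)) p[which.max(p[, 2]), 1]
                        else 0, numeric(1)),
    basePeakIntensity = vapply(pk, function(p) if (nrow(p)) max(p[, 2])
                               else 0, numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = scans$metadata$mass_range[1],
    highMZ = scans$metadata$mass_range[2],
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = sprintf("scan=%d", seq_len(nrow(sc))),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE
  )
  mzR::writeMSData(pk, file = path, header = hdr, outformat = "mzml")
}

#' Read a melting curve from CSV
#'
#' Expects two columns, `temperature_K` and `birefringence`.
#'
#' @param path CSV file.
#' @return Tibble with columns `temperature_K`, `birefringence`.
#' @export
read_melting_curve <- function(path) {
  x <- utils::read.csv(path)
  if (!all(c("temperature_K", "birefringence") %in% names(x))) {
    stop("melting curve CSV must have columns temperature_K, birefringence",
         call. = FALSE)
  }
  validate_melting_curve(tibble::as_tibble(x))
}

#' Write a melting curve to CSV
#' @param curve Tibble with `temperature_K` and `birefringence`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_melting_curve <- function(curve, path) {
  utils::write.csv(curve[, c("temperature_K", "birefringence")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
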