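## Tabular interchange layer. Everything is TSV with one header line;
## frames are 0-indexed on disk and internally.

read_tsv <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = TRUE,
                    na.strings = c("NA", ""))
}

write_tsv <- function(x, path) {
  x <- as.data.frame(x)
  ## %.17g round-trips doubles exactly through read/parse
  for (j in seq_along(x)) {
    if (is.double(x[[j]])) {
      v <- sprintf("%.17g", x[[j]])
      v[is.na(x[[j]])] <- NA_character_
      x[[j]] <- v
    }
  }
  data.table::fwrite(x, path, sep = "\t", na = "NA", quote = FALSE)
}

manifest_cols <- c("subject_id", "group", "severity", "tr_s", "n_frames",
                   "timeseries_path", "motion_path")

#' Read and validate a cohort
#'
#' Reads a cohort manifest (`subject_id`, `group`, `severity`, `tr_s`,
#' `n_frames`, `timeseries_path`, `motion_path`), an ROI-to-network map
#' (`roi_id`, `network_label`, optional `x_mm`,`y_mm`,`z_mm`), and every
#' referenced per-subject ROI time-series and framewise-displacement
#' table. Subjects failing validation (missing files, dimension
#' mismatches, missing values, too few frames) are dropped and recorded
#' with reasons; structural errors in the manifest or map (duplicate
#' subject ids, an ROI in two networks, missing columns) abort.
#'
#' @param manifest_path path to the manifest TSV.
#' @param map_path path to the ROI map TSV.
#' @param min_frames minimum frames for a valid series (default 64, the
#'   floor for three stationary-wavelet levels with usable pattern
#'   counts).
#' @param strict_map require the 11 canonical networks (default `TRUE`).
#' @return An object of class `rsnec_cohort`: list with `manifest`
#'   (valid subjects), `map`, `series` (named list of T x R matrices),
#'   `motion` (named list of data.frames `fd_mm`, `flag`), and a
#'   `rejected` attribute (data.frame subject_id/reason).
#' @export
read_cohort <- function(manifest_path, map_path, min_frames = 64L,
                        strict_map = TRUE) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path,
                                        call. = FALSE)
  if (!file.exists(map_path)) stop("ROI map not found: ", map_path,
                                   call. = FALSE)
  man <- as.data.frame(read_tsv(manifest_path))
  missing_cols <- setdiff(manifest_cols, names(man))
  if (length(missing_cols))
    stop("manifest missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(man$subject_id))
    stop("duplicate subject_id in manifest: ",
         man$subject_id[duplicated(man$subject_id)][1L], call. = FALSE)
  if (any(!is.finite(man$tr_s)) || any(man$tr_s <= 0))
    stop("manifest tr_s must be positive", call. = FALSE)

  mp <- as.data.frame(read_tsv(map_path))
  if (!all(c("roi_id", "network_label") %in% names(mp)))
    stop("ROI map missing roi_id/network_label columns", call. = FALSE)
  coords <- if (all(c("x_mm", "y_mm", "z_mm") %in% names(mp)))
    as.matrix(mp[, c("x_mm", "y_mm", "z_mm")]) else NULL
  map <- network_map(mp$roi_id, mp$network_label, coords, strict = strict_map)
  R <- nrow(map)

  base <- dirname(manifest_path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)

  series <- list(); motion <- list()
  keep <- logical(nrow(man)); reasons <- character(0); rej_ids <- character(0)
  reject <- function(id, why) {
    rej_ids <<- c(rej_ids, id); reasons <<- c(reasons, why)
  }
  for (i in seq_len(nrow(man))) {
    id <- as.character(man$subject_id[i])
    tsp <- resolve(man$timeseries_path[i]); mop <- resolve(man$motion_path[i])
    if (!file.exists(tsp)) { reject(id, "timeseries file missing"); next }
    if (!file.exists(mop)) { reject(id, "motion file missing"); next }
    ts <- as.matrix(read_tsv(tsp))
    if (ncol(ts) != R) {
      reject(id, sprintf("timeseries has %d ROI columns, map has %d",
                         ncol(ts), R)); next
    }
    if (nrow(ts) != man$n_frames[i]) {
      reject(id, sprintf("timeseries has %d frames, manifest declares %d",
                         nrow(ts), man$n_frames[i])); next
    }
    if (nrow(ts) < min_frames) {
      reject(id, sprintf("only %d frames (< %d)", nrow(ts), min_frames)); next
    }
    if (anyNA(ts)) { reject(id, "missing values in timeseries"); next }
    mo <- as.data.frame(read_tsv(mop))
    if (!all(c("frame", "fd_mm") %in% names(mo))) {
      reject(id, "motion table missing frame/fd_mm columns"); next
    }
    if (nrow(mo) != nrow(ts)) {
      reject(id, "motion series length differs from timeseries"); next
    }
    storage.mode(ts) <- "double"
    series[[id]] <- ts
    motion[[id]] <- data.frame(fd_mm = as.numeric(mo$fd_mm),
                               flag = rep(0L, nrow(mo)))
    keep[i] <- TRUE
  }
  rejected <- data.frame(subject_id = rej_ids, reason = reasons,
                         stringsAsFactors = FALSE)
  cohort <- structure(
    list(manifest = man[keep, , drop = FALSE], map = map,
         series = series, motion = motion),
    rejected = rejected, class = "rsnec_cohort")
  cohort
}

#' @export
print.rsnec_cohort <- function(x, ...) {
  cat(sprintf("rsnec cohort: %d subjects, %d ROIs, %d networks\n",
              nrow(x$manifest), nrow(x$map), length(map_networks(x$map))))
  rej <- attr(x, "rejected")
  if (!is.null(rej) && nrow(rej))
    cat(sprintf("  (%d subject(s) rejected at read time)\n", nrow(rej)))
  invisible(x)
}

#' Recompute motion flags and exclude high-motion subjects
#'
#' Flags are always re-derived from the framewise displacement series at
#' `fd_threshold` (never trusted from disk); subjects whose flagged-frame
#' fraction exceeds `max_flag_fraction` are removed. Idempotent.
#'
#' @param cohort an `rsnec_cohort`.
#' @param fd_threshold framewise displacement threshold in mm
#'   (default 0.3).
#' @param max_flag_fraction maximum tolerated flagged fraction
#'   (default 0.10).
#' @return The filtered cohort; excluded subjects are appended to the
#'   `rejected` attribute with the flagged fraction in the reason.
#' @export
apply_exclusions <- function(cohort, fd_threshold = 0.3,
                             max_flag_fraction = 0.10) {
  stopifnot(inherits(cohort, "rsnec_cohort"))
  ids <- as.character(cohort$manifest$subject_id)
  frac <- numeric(length(ids)); names(frac) <- ids
  for (id in ids) {
    fl <- as.integer(cohort$motion[[id]]$fd_mm > fd_threshold)
    cohort$motion[[id]]$flag <- fl
    frac[id] <- mean(fl)
  }
  drop <- ids[frac > max_flag_fraction]
  keep <- setdiff(ids, drop)
  if (!length(keep)) warning("all subjects excluded by motion criterion")
  rej <- attr(cohort, "rejected")
  if (length(drop)) {
    rej <- rbind(rej, data.frame(
      subject_id = drop,
      reason = sprintf("flagged fraction %.3f > %.3f", frac[drop],
                       max_flag_fraction),
      stringsAsFactors = FALSE))
  }
  cohort$manifest <- cohort$manifest[
    as.character(cohort$manifest$subject_id) %in% keep, , drop = FALSE]
  cohort$series <- cohort$series[keep]
  cohort$motion <- cohort$motion[keep]
  attr(cohort, "rejected") <- rej
  cohort
}

#' Mean time series within spherical ROIs of a 4-D volume
#'
#' Convenience extractor for volumetric data already loaded as an array.
#' Voxel membership uses the Euclidean distance (mm) from the voxel
#' center, after applying the affine, to each ROI center; no
#' partial-volume weighting. `radius = 0` selects the single nearest
#' voxel.
#'
#' @param volume 4-D numeric array (x, y, z, frame).
#' @param affine 4x4 voxel-index-to-mm affine (0-based voxel indices).
#' @param coordinates numeric matrix (n_roi x 3) of mm coordinates.
#' @param radius sphere radius in mm (default 5, i.e. 10 mm diameter).
#' @return T x n_roi matrix of per-frame sphere means.
#' @export
extract_roi_means <- function(volume, affine, coordinates, radius = 5) {
  stopifnot(length(dim(volume)) == 4, is.matrix(affine),
            all(dim(affine) == c(4, 4)))
  coordinates <- matrix(as.numeric(coordinates), ncol = 3)
  d <- dim(volume)
  grid <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                                k = 0:(d[3] - 1)))
  mm <- cbind(grid, 1) %*% t(affine)      # voxel centers in mm
  mm <- mm[, 1:3, drop = FALSE]
  nT <- d[4]
  flat <- matrix(volume, nrow = prod(d[1:3]), ncol = nT)
  out <- matrix(NA_real_, nrow = nT, ncol = nrow(coordinates))
  ## field-of-view check: inverse-map each center into voxel index space
  inv <- solve(affine)
  for (q in seq_len(nrow(coordinates))) {
    ctr <- coordinates[q, ]
    vox <- as.numeric(inv %*% c(ctr, 1))[1:3]
    if (any(vox < -0.5) || any(vox > d[1:3] - 0.5))
      stop(sprintf("ROI %d center (%.1f, %.1f, %.1f) outside the volume",
                   q, ctr[1], ctr[2], ctr[3]), call. = FALSE)
    dist2 <- (mm[, 1] - ctr[1])^2 + (mm[, 2] - ctr[2])^2 + (mm[, 3] - ctr[3])^2
    sel <- if (radius > 0) which(dist2 <= radius^2) else which.min(dist2)
    if (!length(sel)) sel <- which.min(dist2)   # empty sphere: nearest voxel
    out[, q] <- if (length(sel) == 1L) flat[sel, ]
                else colMeans(flat[sel, , drop = FALSE])
  }
  colnames(out) <- rownames(coordinates)
  out
}

#' Write a cohort to disk in the package's TSV layout
#'
#' Produces `manifest.tsv`, `roi_map.tsv`, and per-subject
#' `ts_<id>.tsv` / `motion_<id>.tsv` files under `dir`. Numeric values
#' are written with shortest round-trippable precision, so
#' [read_cohort()] recovers the matrices bit-for-bit.
#'
#' @param cohort an `rsnec_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "rsnec_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  man$timeseries_path <- paste0("ts_", man$subject_id, ".tsv")
  man$motion_path <- paste0("motion_", man$subject_id, ".tsv")
  for (id in as.character(man$subject_id)) {
    ts <- as.data.frame(cohort$series[[id]])
    names(ts) <- as.character(cohort$map$roi_id)
    write_tsv(ts, file.path(dir, paste0("ts_", id, ".tsv")))
    mo <- cohort$motion[[id]]
    write_tsv(data.frame(frame = seq_len(nrow(mo)) - 1L, fd_mm = mo$fd_mm),
              file.path(dir, paste0("motion_", id, ".tsv")))
  }
  write_tsv(man, file.path(dir, "manifest.tsv"))
  mp <- as.data.frame(cohort$map)
  write_tsv(mp, file.path(dir, "roi_map.tsv"))
  invisible(dir)
}
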