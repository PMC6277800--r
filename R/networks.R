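#' Canonical resting-state network order
#'
#' The 11 RSN labels in the fixed order used for every network-indexed
#' object in the package (entropy profiles, feature slots, contrast
#' vectors). Sensory networks come first, then attention/control, then
#' default-mode/salience/fronto-parietal, then subcortical.
#'
#' @return Character vector of 11 network labels.
#' @export
canonical_networks <- function() {
  c("SM", "SM-lat", "VIS", "AUD", "DAN", "VAN", "CO", "DMN", "SAL", "FP", "SUB")
}

#' Networks treated as "sensory" for the PCA sign convention
#' @return Character vector (subset of [canonical_networks()]).
#' @export
sensory_networks <- function() c("SM", "SM-lat", "VIS", "AUD")

## Slot layout for the network-pair feature vector: n intra slots in
## canonical order, then the upper triangle (k < l) row-major.
slot_index <- function(networks) {
  n <- length(networks)
  intra <- data.frame(k = seq_len(n), l = seq_len(n))
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ut <- ut[order(ut[, "row"], ut[, "col"]), , drop = FALSE]
  inter <- data.frame(k = ut[, "row"], l = ut[, "col"])
  rbind(intra, inter)
}

#' Feature-slot names for a set of networks
#'
#' @param networks character vector of network labels (default the
#'   canonical 11).
#' @return Character vector of length `n + n*(n-1)/2`: intra slots
#'   `"NET:NET"` then inter slots `"NETk:NETl"` (k < l, row-major).
#' @export
slot_names <- function(networks = canonical_networks()) {
  idx <- slot_index(networks)
  paste0(networks[idx$k], ":", networks[idx$l])
}

#' Number of feature slots for n networks
#' @param n_networks integer number of networks.
#' @return `n + n*(n-1)/2`.
#' @export
n_slots <- function(n_networks) n_networks + n_networks * (n_networks - 1L) / 2L

#' Construct an ROI-to-network map
#'
#' @param roi_id integer ROI identifiers (unique).
#' @param network_label network label per ROI.
#' @param coords optional numeric matrix (R x 3) of MNI mm coordinates.
#' @param strict if `TRUE` (cohort-level contract) require exactly the 11
#'   canonical networks, each with at least 2 ROIs; if `FALSE` accept any
#'   set of >= 2 networks with >= 2 ROIs each (used by toy analyses).
#' @return A `network_map` object (data.frame with attributes).
#' @export
network_map <- function(roi_id, network_label, coords = NULL, strict = TRUE) {
  roi_id <- as.integer(roi_id)
  network_label <- as.character(network_label)
  if (length(roi_id) != length(network_label))
    stop("roi_id and network_label lengths differ", call. = FALSE)
  if (anyDuplicated(roi_id)) {
    dup <- roi_id[duplicated(roi_id)][1L]
    stop(sprintf("ROI %d assigned more than once in the network map", dup),
         call. = FALSE)
  }
  nets <- unique(network_label)
  if (strict) {
    missing <- setdiff(canonical_networks(), nets)
    extra <- setdiff(nets, canonical_networks())
    if (length(missing) || length(extra))
      stop("strict network map requires exactly the 11 canonical networks; ",
           if (length(missing)) paste0("missing: ", paste(missing, collapse = ", "), " "),
           if (length(extra)) paste0("unknown: ", paste(extra, collapse = ", ")),
           call. = FALSE)
    nets <- canonical_networks()
  } else {
    if (length(nets) < 2) stop("need at least 2 networks", call. = FALSE)
    ## keep first-appearance order unless all labels are canonical
    if (all(nets %in% canonical_networks()))
      nets <- canonical_networks()[canonical_networks() %in% nets]
  }
  counts <- table(factor(network_label, levels = nets))
  if (any(counts < 2)) {
    bad <- names(counts)[counts < 2]
    stop("network(s) with fewer than 2 ROIs: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  map <- data.frame(roi_id = roi_id, network_label = network_label,
                    stringsAsFactors = FALSE)
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    stopifnot(nrow(coords) == length(roi_id), ncol(coords) == 3)
    map$x_mm <- coords[, 1]; map$y_mm <- coords[, 2]; map$z_mm <- coords[, 3]
  }
  attr(map, "networks") <- nets
  class(map) <- c("network_map", "data.frame")
  map
}

map_networks <- function(map) attr(map, "networks")
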