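# Desk-scale core of the morphologically matched multi-atlas (MAGMA)
# labelling procedure: exemplar selection by Jacobian-determinant similarity,
# similarity-weighted majority-vote label fusion, and volume extraction.
# Registration is out of scope: all inputs must already share one voxel grid.

#' Morphological similarity of candidate Jacobian maps to a target
#'
#' Pearson correlation, within a brain mask, between the target's
#' Jacobian-determinant field and each candidate's. Jacobians are
#' ratio-scaled, so the correlation is computed on log values by default.
#'
#' @param target_jac target Jacobian-determinant array (values > 0 in mask).
#' @param candidate_jacs list of candidate Jacobian arrays on the same grid.
#' @param mask logical array; at least 2 voxels must be TRUE.
#' @param log_scale correlate log-Jacobians (default) or raw values.
#' @return numeric vector of per-candidate correlations. A zero-variance
#'   vector yields `NA` with a warning; `NA` scores rank last downstream.
#' @export
jacobian_similarity <- function(target_jac, candidate_jacs, mask,
                                log_scale = TRUE) {
  stopifnot(is.list(candidate_jacs), sum(mask) >= 2)
  tv <- target_jac[mask]
  if (!all(is.finite(tv))) stop("non-finite target Jacobian values inside mask")
  if (log_scale) {
    if (any(tv <= 0)) stop("Jacobian determinants must be > 0 inside the mask")
    tv <- log(tv)
  }
  vapply(seq_along(candidate_jacs), function(k) {
    cv <- candidate_jacs[[k]][mask]
    if (!all(is.finite(cv))) stop("non-finite Jacobian values in candidate ", k)
    if (log_scale) {
      if (any(cv <= 0)) stop("Jacobian determinants must be > 0 inside the mask (candidate ", k, ")")
      cv <- log(cv)
    }
    if (stats::sd(cv) == 0 || stats::sd(tv) == 0) {
      warning("zero-variance Jacobian vector for candidate ", k,
              "; similarity undefined, candidate will rank last")
      return(NA_real_)
    }
    stats::cor(tv, cv)
  }, numeric(1))
}

#' Select the k morphologically most similar exemplars
#'
#' Top-k candidates by similarity score, descending; ties (and `NA` scores,
#' which always rank last) are broken by candidate order, so selection is
#' deterministic.
#'
#' @param scores per-candidate similarity (e.g. from [jacobian_similarity()]).
#' @param k number of exemplars; if `k` exceeds the number of candidates, all
#'   are selected with a warning.
#' @return list of class `exemplar_selection`: `chosen` (candidate indices,
#'   most similar first), `scores` (all input scores), `k`.
#' @export
select_exemplars <- function(scores, k = 10) {
  stopifnot(k >= 1)
  n <- length(scores)
  if (k > n) {
    warning("k = ", k, " exceeds the ", n, " available candidates; selecting all")
    k <- n
  }
  ord <- order(-scores, seq_along(scores), na.last = TRUE)
  sel <- list(chosen = ord[seq_len(k)], scores = scores, k = k)
  class(sel) <- "exemplar_selection"
  sel
}

#' Similarity-weighted majority-vote label fusion
#'
#' Every label map of every chosen exemplar casts a vote at each voxel,
#' weighted by the local intensity similarity between that exemplar's
#' intensity image and the target: `w = 1 / (epsilon + local mean squared
#' intensity difference)` over a cubic patch. The fused label is the argmax
#' of summed weights; ties go to the lowest label code, so the result is
#' deterministic and invariant to atlas order.
#'
#' @param stack an `atlas_stack` (target intensity, candidate intensities and
#'   label maps on a common grid).
#' @param selection an `exemplar_selection`; all label sets of each chosen
#'   candidate contribute.
#' @param patch_radius cubic patch radius in voxels (1 = 3^3 patch).
#' @param epsilon additive constant guarding against zero patch difference.
#' @return list of class `label_map`: `labels` (integer array) and
#'   `region_dictionary` (code -> name, carried from the stack when present).
#' @export
fuse_labels <- function(stack, selection, patch_radius = 1, epsilon = 1e-6) {
  stopifnot(inherits(selection, "exemplar_selection"))
  if (length(selection$chosen) == 0) stop("empty exemplar selection")
  dims <- dim(stack$target_intensity)
  for (k in selection$chosen) {
    if (!identical(dim(stack$candidate_intensities[[k]]), dims))
      stop("candidate ", k, " intensity grid does not match the target grid")
    for (lab in stack$candidate_labels[[k]])
      if (!identical(dim(lab), dims))
        stop("candidate ", k, " label grid does not match the target grid")
  }

  codes <- sort(unique(unlist(lapply(selection$chosen, function(k)
    lapply(stack$candidate_labels[[k]], function(l) unique(as.integer(l)))))))
  vote <- array(0, c(dims, length(codes)))
  nvox <- prod(dims)

  for (k in selection$chosen) {
    d2 <- (stack$candidate_intensities[[k]] - stack$target_intensity)^2
    w <- 1 / (epsilon + box_mean_3d(d2, patch_radius))
    for (lab in stack$candidate_labels[[k]]) {
      li <- match(as.integer(lab), codes)
      vote[seq_len(nvox) + (li - 1) * nvox] <-
        vote[seq_len(nvox) + (li - 1) * nvox] + w
    }
  }

  vm <- matrix(vote, nvox, length(codes))
  best <- max.col(vm, ties.method = "first")  # codes sorted -> lowest code wins ties
  labels <- array(codes[best], dims)

  dict <- stack$region_dictionary
  if (is.null(dict))
    dict <- stats::setNames(paste0("region_", setdiff(codes, 0L)), setdiff(codes, 0L))
  out <- list(labels = labels, region_dictionary = dict)
  class(out) <- "label_map"
  out
}

#' Regional volumes from a label map
#'
#' `volume(region) = voxel count * prod(voxel_dims)`; intracranial volume
#' (ICV) is the total volume of all nonzero labels, so per-region volumes sum
#' exactly to ICV.
#'
#' @param label_map a `label_map` (or a bare integer array plus a
#'   `region_dictionary` argument).
#' @param voxel_dims mm per axis, all > 0.
#' @param region_dictionary optional named vector (code -> region name)
#'   overriding the map's dictionary.
#' @return list of class `voi_record`: `volumes` (named mm^3 vector) and `icv`.
#' @export
extract_volumes <- function(label_map, voxel_dims = c(1, 1, 1),
                            region_dictionary = NULL) {
  if (inherits(label_map, "label_map")) {
    labels <- label_map$labels
    if (is.null(region_dictionary)) region_dictionary <- label_map$region_dictionary
  } else labels <- label_map
  stopifnot(all(voxel_dims > 0), length(voxel_dims) == 3)
  vv <- prod(voxel_dims)
  counts <- table(labels[labels != 0])
  if (length(counts) == 0) {
    out <- list(volumes = stats::setNames(numeric(0), character(0)), icv = 0)
    class(out) <- "voi_record"
    return(out)
  }
  codes <- names(counts)
  if (!is.null(region_dictionary)) {
    missing <- setdiff(codes, names(region_dictionary))
    if (length(missing))
      stop("label code(s) missing from region dictionary: ",
           paste(missing, collapse = ", "))
    nm <- unname(region_dictionary[codes])
  } else nm <- paste0("region_", codes)
  volumes <- stats::setNames(as.numeric(counts) * vv, nm)
  out <- list(volumes = volumes, icv = sum(volumes))
  class(out) <- "voi_record"
  out
}

#' Run the full desk-scale labelling chain on an atlas stack
#'
#' Jacobian similarity -> exemplar selection -> weighted-vote fusion ->
#' volume extraction.
#'
#' @param stack an `atlas_stack` with a `target_jacobian` field.
#' @param k exemplar count (study condition: 10 exemplars, 5 label sets each).
#' @param ... passed to [fuse_labels()].
#' @return list: `scores`, `selection`, `label_map`, `voi_record`.
#' @export
magma_label <- function(stack, k = 10, ...) {
  scores <- jacobian_similarity(stack$target_jacobian,
                                stack$candidate_jacobians, stack$mask)
  selection <- select_exemplars(scores, k)
  lm <- fuse_labels(stack, selection, ...)
  list(scores = scores, selection = selection, label_map = lm,
       voi_record = extract_volumes(lm, stack$voxel_dims))
}

#' Read/write a region dictionary as two-column TSV (code, name)
#' @param path TSV file path.
#' @return named character vector (names are label codes).
#' @export
read_region_dictionary <- function(path) {
  d <- utils::read.delim(path, header = TRUE, colClasses = c("integer", "character"))
  stats::setNames(d[[2]], d[[1]])
}

#' @rdname read_region_dictionary
#' @param dict named character vector (code -> region name).
#' @export
write_region_dictionary <- function(dict, path) {
  utils::write.table(data.frame(code = names(dict), name = unname(dict)),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
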