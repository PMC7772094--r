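# Voxel-array helpers shared by the atlas simulator and the fusion core.

# Shift a 3D array by `offset` voxels along `dim`, zero-filling the edge.
shift3d <- function(a, offset, dim) {
  if (offset == 0) return(a)
  d <- base::dim(a)
  out <- array(0, d)
  src <- dst <- lapply(d, seq_len)
  n <- d[dim]
  if (abs(offset) >= n) return(out)
  if (offset > 0) {
    dst[[dim]] <- (offset + 1):n; src[[dim]] <- 1:(n - offset)
  } else {
    dst[[dim]] <- 1:(n + offset); src[[dim]] <- (1 - offset):n
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Local mean over a cubic (2r+1)^3 patch, truncated at array edges.
box_mean_3d <- function(a, radius = 1) {
  stopifnot(length(dim(a)) == 3, radius >= 0)
  s <- a
  cnt <- array(1, dim(a))
  for (d in 1:3) {
    acc_s <- s; acc_c <- cnt
    for (o in seq_len(radius)) {
      acc_s <- acc_s + shift3d(s, o, d) + shift3d(s, -o, d)
      acc_c <- acc_c + shift3d(cnt, o, d) + shift3d(cnt, -o, d)
    }
    s <- acc_s; cnt <- acc_c
  }
  s / cnt
}

# Smooth Gaussian-ish random field: iterated box filtering of white noise,
# standardized to zero mean / unit SD.
smooth_field <- function(grid_shape, passes = 3, radius = 2) {
  f <- array(stats::rnorm(prod(grid_shape)), grid_shape)
  for (p in seq_len(passes)) f <- box_mean_3d(f, radius)
  (f - mean(f)) / stats::sd(f)
}

#' Simulate a synthetic multi-atlas stack
#'
#' Produces the inputs the label-fusion core consumes, with controllable
#' ground truth: a smooth target intensity image; `n_candidates` candidate
#' intensities (target plus smooth perturbations); `n_label_sets` label maps
#' per candidate, each the true parcellation with a controlled fraction of
#' in-mask voxels reassigned to another label; per-candidate
#' Jacobian-determinant maps whose log-scale Pearson correlation with the
#' target's map (within the mask) equals a prescribed value exactly (by
#' Gram-Schmidt construction); and an ellipsoidal brain mask.
#'
#' @param grid_shape integer length-3 voxel grid (desk scale, e.g. 32^3).
#' @param n_candidates number of candidate atlases.
#' @param n_label_sets label maps per candidate.
#' @param n_regions number of foreground labels in the true parcellation.
#' @param disagreement fraction of in-mask voxels whose label is corrupted in
#'   each candidate label map (0 = all maps identical to the truth).
#' @param jacobian_correlations length-`n_candidates` target correlations of
#'   candidate log-Jacobian fields with the target's; default a descending
#'   ladder on (0, 1).
#' @param intensity_perturbation_sd SD of the smooth intensity perturbation,
#'   relative to the target intensity SD.
#' @param voxel_dims voxel size in mm per axis.
#' @param seed integer RNG seed.
#' @return list of class `atlas_stack`: `target_intensity`,
#'   `candidate_intensities`, `candidate_labels` (list of lists),
#'   `candidate_jacobians`, `target_jacobian`, `mask`, `voxel_dims`,
#'   `true_labels`, `region_dictionary`, `jacobian_correlations`.
#' @export
simulate_atlas_stack <- function(grid_shape = c(32, 32, 32),
                                 n_candidates = 10,
                                 n_label_sets = 5,
                                 n_regions = 4,
                                 disagreement = 0.05,
                                 jacobian_correlations = NULL,
                                 intensity_perturbation_sd = 0.2,
                                 voxel_dims = c(1, 1, 1),
                                 seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 8),
            n_candidates >= 1, n_label_sets >= 1, n_regions >= 1,
            disagreement >= 0, disagreement <= 1)
  if (is.null(jacobian_correlations))
    jacobian_correlations <- seq(0.95, 0.1, length.out = n_candidates)
  stopifnot(length(jacobian_correlations) == n_candidates,
            all(abs(jacobian_correlations) < 1))
  set.seed(seed)

  # ellipsoidal mask
  ax <- lapply(grid_shape, function(n) (seq_len(n) - (n + 1) / 2) / (n / 2 - 1))
  mask <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`) <= 0.85^2
  n_in <- sum(mask)
  stopifnot(n_in > n_regions * 10)

  target <- 100 + 20 * smooth_field(grid_shape)

  # true parcellation: quantile bands of a smooth field inside the mask
  part <- smooth_field(grid_shape)
  q <- stats::quantile(part[mask], probs = seq(0, 1, length.out = n_regions + 1))
  true_labels <- array(0L, grid_shape)
  lab_in <- as.integer(cut(part[mask], breaks = q, include.lowest = TRUE))
  true_labels[mask] <- lab_in

  # target log-Jacobian field, standardized over the mask
  zt <- smooth_field(grid_shape)
  zt_m <- scale(zt[mask])[, 1]
  target_jac <- array(1, grid_shape)
  target_jac[mask] <- exp(0.1 * zt_m)

  cand_int <- cand_jac <- vector("list", n_candidates)
  cand_lab <- vector("list", n_candidates)
  for (k in seq_len(n_candidates)) {
    cand_int[[k]] <- target +
      intensity_perturbation_sd * 20 * smooth_field(grid_shape)

    # exact in-mask correlation via Gram-Schmidt on the masked vectors
    e <- smooth_field(grid_shape)[mask]
    e <- e - zt_m * sum(e * zt_m) / sum(zt_m^2)
    e <- scale(e)[, 1]
    r <- jacobian_correlations[k]
    f <- r * zt_m + sqrt(1 - r^2) * e
    jac <- array(1, grid_shape)
    jac[mask] <- exp(0.1 * f)
    cand_jac[[k]] <- jac

    sets <- vector("list", n_label_sets)
    for (s in seq_len(n_label_sets)) {
      lab <- true_labels
      n_flip <- round(disagreement * n_in)
      if (n_flip > 0) {
        flip <- sample(which(mask), n_flip)
        shift <- sample(n_regions - 1, n_flip, replace = TRUE)
        lab[flip] <- as.integer(1L + (lab[flip] - 1L + shift) %% n_regions)
      }
      sets[[s]] <- lab
    }
    cand_lab[[k]] <- sets
  }

  stack <- list(
    target_intensity = target,
    candidate_intensities = cand_int,
    candidate_labels = cand_lab,
    candidate_jacobians = cand_jac,
    target_jacobian = target_jac,
    mask = mask,
    voxel_dims = voxel_dims,
    true_labels = true_labels,
    region_dictionary = stats::setNames(paste0("region_", seq_len(n_regions)),
                                        seq_len(n_regions)),
    jacobian_correlations = jacobian_correlations
  )
  class(stack) <- "atlas_stack"
  stack
}

#' Write an atlas stack as NIfTI files plus a JSON manifest
#'
#' @param stack an `atlas_stack`.
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest path.
#' @export
write_atlas_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "atlas_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(a, name) {
    p <- file.path(dir, paste0(name, ".nii.gz"))
    im <- RNifti::asNifti(a * 1)
    RNifti::pixdim(im) <- stack$voxel_dims
    RNifti::writeNifti(im, p)
    basename(p)
  }
  manifest <- list(
    target_intensity = wr(stack$target_intensity, "target_intensity"),
    target_jacobian = wr(stack$target_jacobian, "target_jacobian"),
    mask = wr(stack$mask, "mask"),
    voxel_dims = stack$voxel_dims,
    candidates = lapply(seq_along(stack$candidate_intensities), function(k) list(
      intensity = wr(stack$candidate_intensities[[k]], sprintf("cand%02d_intensity", k)),
      jacobian = wr(stack$candidate_jacobians[[k]], sprintf("cand%02d_jacobian", k)),
      labels = vapply(seq_along(stack$candidate_labels[[k]]), function(s)
        wr(stack$candidate_labels[[k]][[s]], sprintf("cand%02d_labels%d", k, s)),
        character(1))
    ))
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an atlas stack written by [write_atlas_stack()]
#'
#' @param dir directory containing `manifest.json` and the NIfTI volumes.
#' @return an `atlas_stack` (without ground-truth fields).
#' @export
read_atlas_stack <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = FALSE)
  rd <- function(name) {
    a <- RNifti::readNifti(file.path(dir, name))
    array(as.numeric(a), dim(a))
  }
  stack <- list(
    target_intensity = rd(man$target_intensity),
    target_jacobian = rd(man$target_jacobian),
    mask = rd(man$mask) > 0.5,
    voxel_dims = as.numeric(unlist(man$voxel_dims)),
    candidate_intensities = lapply(man$candidates, function(c) rd(c$intensity)),
    candidate_jacobians = lapply(man$candidates, function(c) rd(c$jacobian)),
    candidate_labels = lapply(man$candidates, function(c)
      lapply(c$labels, function(f) {
        l <- rd(f); storage.mode(l) <- "integer"; l
      }))
  )
  class(stack) <- "atlas_stack"
  stack
}
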