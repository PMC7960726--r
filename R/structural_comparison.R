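# Structural comparison of atomic models: C-alpha pairing, Kabsch
# superposition, displacement fields, distance-difference matrices, radius
# of gyration, and bootstrap coordinate-uncertainty estimation.

#' Pair the C-alpha atoms of two models
#'
#' Matches C-alpha atoms by (chain, residue number) — isomorphous models of
#' the same protein, no sequence alignment — ordered chain-then-residue.
#' Residues present in only one model are listed in the report.
#'
#' @param a,b [structure_model()] objects.
#' @return object of class `paired_ca`: list with `keys` (chain, resno),
#'   `xyz_a`, `xyz_b` (n x 3 matrices) and `unmatched_a`/`unmatched_b`.
#' @export
pair_models <- function(a, b) {
  stopifnot(inherits(a, "structure_model"), inherits(b, "structure_model"))
  ca_a <- ca_atoms(a)
  ca_b <- ca_atoms(b)
  key_a <- paste(ca_a$chain, ca_a$resno)
  key_b <- paste(ca_b$chain, ca_b$resno)
  common <- intersect(key_a, key_b)
  if (length(common) == 0L)
    stop("no common (chain, residue) C-alpha pairs between the models",
         call. = FALSE)
  ia <- match(common, key_a)
  ord <- order(ca_a$chain[ia], ca_a$resno[ia])
  common <- common[ord]
  ia <- ia[ord]
  ib <- match(common, key_b)
  structure(list(
    keys = data.frame(chain = ca_a$chain[ia], resno = ca_a$resno[ia],
                      stringsAsFactors = FALSE),
    xyz_a = as.matrix(ca_a[ia, c("x", "y", "z")]),
    xyz_b = as.matrix(ca_b[ib, c("x", "y", "z")]),
    unmatched_a = setdiff(key_a, key_b),
    unmatched_b = setdiff(key_b, key_a)),
    class = "paired_ca")
}

#' @export
print.paired_ca <- function(x, ...) {
  cat(sprintf("paired_ca: %d residue pairs (%d only in A, %d only in B)\n",
              nrow(x$keys), length(x$unmatched_a), length(x$unmatched_b)))
  invisible(x)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Proper-rotation least-squares superposition of the paired coordinates:
#' the optimal rotation is obtained from the SVD of the covariance matrix
#' with the determinant corrected to +1 (reflections disallowed). Model B
#' is rotated/translated onto model A.
#'
#' @param paired a [pair_models()] result (>= 3 non-collinear pairs).
#' @return list with `rotation` (3 x 3, det +1), `translation`, `rmsd`
#'   (Angstrom, after superposition) and `xyz_b_aligned`.
#' @export
superpose <- function(paired) {
  stopifnot(inherits(paired, "paired_ca"))
  A <- paired$xyz_a
  B <- paired$xyz_b
  if (nrow(A) < 3) stop("need at least 3 pairs", call. = FALSE)
  ca <- colMeans(A)
  cb <- colMeans(B)
  A0 <- sweep(A, 2, ca)
  B0 <- sweep(B, 2, cb)
  H <- t(B0) %*% A0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) stop("degenerate geometry: superposition undefined",
                   call. = FALSE)
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  Baln <- sweep(B0 %*% t(R), 2, ca, `+`)
  rmsd <- sqrt(mean(rowSums((Baln - A)^2)))
  list(rotation = R, translation = ca - as.numeric(R %*% cb), rmsd = rmsd,
       xyz_b_aligned = Baln)
}

#' Per-residue C-alpha displacement field
#'
#' Vectors B - A per paired C-alpha, optionally after rigid superposition
#' of B onto A (default). The exported arrow columns are scaled by
#' `arrow_scale` for visualization only; statistics always use the
#' unscaled vectors.
#'
#' @param paired a [pair_models()] result.
#' @param superpose_first superpose B onto A before differencing
#'   (default TRUE).
#' @param arrow_scale visual arrow magnification (default 10).
#' @return data frame: chain, resno, dx, dy, dz, length, and `arrow_*`
#'   columns (scaled).
#' @export
displacement_field <- function(paired, superpose_first = TRUE,
                               arrow_scale = 10) {
  stopifnot(inherits(paired, "paired_ca"))
  xyz_b <- if (superpose_first) superpose(paired)$xyz_b_aligned else
    paired$xyz_b
  v <- xyz_b - paired$xyz_a
  out <- data.frame(paired$keys, dx = v[, 1], dy = v[, 2], dz = v[, 3],
                    length = sqrt(rowSums(v^2)))
  out$arrow_dx <- arrow_scale * out$dx
  out$arrow_dy <- arrow_scale * out$dy
  out$arrow_dz <- arrow_scale * out$dz
  out
}

#' C-alpha distance-difference matrix
#'
#' `D_ij = d_ij(B) - d_ij(A)` over all paired C-alpha atoms (no
#' superposition needed; pairwise distances are rigid-motion invariant),
#' plus the relative form `D_ij / d_ij(A)` and, as compaction/expansion
#' summary, the per-residue sum of relative changes (negative = the
#' residue moves closer to the rest of the molecule).
#'
#' @param paired a [pair_models()] result.
#' @return list with `delta` (Angstrom), `relative`, and
#'   `per_residue_sum`.
#' @export
distance_difference_matrix <- function(paired) {
  stopifnot(inherits(paired, "paired_ca"))
  da <- as.matrix(stats::dist(paired$xyz_a))
  db <- as.matrix(stats::dist(paired$xyz_b))
  delta <- db - da
  rel <- delta
  nz <- da > 0
  rel[nz] <- delta[nz] / da[nz]
  rel[!nz] <- 0
  lab <- paste(paired$keys$chain, paired$keys$resno)
  dimnames(delta) <- dimnames(rel) <- list(lab, lab)
  list(delta = delta, relative = rel, per_residue_sum = rowSums(rel))
}

#' Radius of gyration
#'
#' `Rg = sqrt(sum w_i |r_i - rbar|^2 / sum w_i)`; unweighted over the
#' C-alpha selection by default (insensitive to side-chain noise).
#'
#' @param model a [structure_model()].
#' @param selection "calpha" (default) or "all".
#' @param mass_weighted weight by a nominal mass column `mass` if present
#'   (default FALSE, uniform weights).
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(model, selection = c("calpha", "all"),
                               mass_weighted = FALSE) {
  stopifnot(inherits(model, "structure_model"))
  selection <- match.arg(selection)
  a <- if (selection == "calpha") ca_atoms(model) else model$atoms
  if (nrow(a) == 0L) stop("empty selection", call. = FALSE)
  w <- if (mass_weighted && !is.null(a$mass)) a$mass else rep(1, nrow(a))
  xyz <- as.matrix(a[c("x", "y", "z")])
  ctr <- colSums(xyz * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, ctr)^2)) / sum(w))
}

#' Surrogate refinement engine: per-atom mean of coordinate observations
#'
#' Maps a multiset of image ids to a model by averaging the per-image
#' coordinate observations (with multiplicity weights). This is the
#' pluggable `refine_engine` contract shipped with the package; a
#' crystallographic refinement program satisfying the same contract can be
#' substituted.
#'
#' @param observations n_atoms x 3 x n_images array (image ids in the
#'   third dimnames).
#' @return function(image_ids) -> n_atoms x 3 coordinate matrix.
#' @export
surrogate_engine <- function(observations) {
  dm <- dim(observations)
  flat <- matrix(observations, dm[1] * dm[2], dm[3])
  ids <- dimnames(observations)[[3]]
  function(image_ids) {
    idx <- match(as.character(image_ids), ids)
    if (anyNA(idx)) stop("unknown image id in resample", call. = FALSE)
    matrix(rowMeans(flat[, idx, drop = FALSE]), dm[1], dm[2])
  }
}

#' Bootstrap ensemble of refined structures
#'
#' Draws `n_boot` resamples of the image pool with replacement (each of
#' the original pool size), refines a model against each with
#' `refine_engine`, and summarises the ensemble by per-atom mean positions
#' and per-coordinate standard deviations — the coordinate-error estimate.
#' If the engine fails on a resample the resample is redrawn once, then
#' the error propagates.
#'
#' @param image_pool vector of image ids (the pool available to the
#'   original refinement).
#' @param refine_engine function(image_ids) -> n x 3 coordinate matrix;
#'   see [surrogate_engine()].
#' @param n_boot ensemble size (>= 2; default 100).
#' @param seed RNG seed.
#' @return object of class `bootstrap_ensemble`: list with `mean` (n x 3),
#'   `sd` (n x 3 per-coordinate SDs), `models` (n x 3 x n_boot),
#'   `resampled_ids`, `seed`, `n_boot`.
#' @export
bootstrap_ensemble <- function(image_pool, refine_engine, n_boot = 100,
                               seed = 1) {
  if (n_boot < 2) stop("n_boot must be >= 2", call. = FALSE)
  m <- length(image_pool)
  if (m < 1) stop("empty image pool", call. = FALSE)
  with_seed(seed, {
    resamples <- vector("list", n_boot)
    models <- NULL
    for (b in seq_len(n_boot)) {
      ids <- sample(image_pool, m, replace = TRUE)
      fit <- tryCatch(refine_engine(ids), error = function(e) e)
      if (inherits(fit, "error")) {          # redraw once, then fail
        ids <- sample(image_pool, m, replace = TRUE)
        fit <- refine_engine(ids)
      }
      if (is.null(models))
        models <- array(NA_real_, dim = c(nrow(fit), 3, n_boot))
      models[, , b] <- fit
      resamples[[b]] <- ids
    }
    structure(list(mean = apply(models, c(1, 2), mean),
                   sd = apply(models, c(1, 2), stats::sd),
                   models = models, resampled_ids = resamples,
                   seed = seed, n_boot = n_boot),
              class = "bootstrap_ensemble")
  })
}

#' @export
print.bootstrap_ensemble <- function(x, ...) {
  cat(sprintf(
    "bootstrap_ensemble: %d members, %d atoms, mean coordinate SD %.4f A\n",
    x$n_boot, nrow(x$mean), mean(x$sd)))
  invisible(x)
}

#' Two-sigma consistency check against a bootstrap ensemble
#'
#' Flags atoms of a reference coordinate set deviating from the ensemble
#' mean by more than twice the bootstrap coordinate SD in any coordinate.
#' (The experimental convention labels the 2-sigma band "the 90% confidence
#' level"; for a normal law 2 sigma is ~95% — the label is reported as-is,
#' the check is literally 2 sigma.) A zero-SD ensemble is flagged as
#' degenerate.
#'
#' @param ensemble a [bootstrap_ensemble()].
#' @param reference_xyz n x 3 coordinate matrix to check.
#' @return list with `within` (logical per atom), `fraction_within`,
#'   `degenerate`, and the label `confidence_label = "90% confidence
#'   level (2 sigma)"`.
#' @export
two_sigma_check <- function(ensemble, reference_xyz) {
  stopifnot(inherits(ensemble, "bootstrap_ensemble"))
  dev <- abs(reference_xyz - ensemble$mean)
  degenerate <- all(ensemble$sd == 0)
  within <- apply(dev <= 2 * ensemble$sd, 1, all)
  list(within = within, fraction_within = mean(within),
       degenerate = degenerate,
       confidence_label = "90% confidence level (2 sigma)")
}

#' Structured comparison report for two models
#'
#' RMSD over paired C-alpha after Kabsch superposition, mean per-atom
#' displacement, radii of gyration, the per-residue compaction summary
#' (sum of relative distance changes), and — when bootstrap ensembles are
#' supplied — the count of residues whose displacement exceeds twice its
#' bootstrap coordinate error.
#'
#' @param a,b [structure_model()] objects.
#' @param ensemble optional [bootstrap_ensemble()] for model B's paired
#'   C-alpha coordinates (coordinate errors).
#' @param superpose_first superpose before displacement statistics
#'   (default TRUE).
#' @return object of class `structure_comparison` (a list).
#' @export
compare_report <- function(a, b, ensemble = NULL, superpose_first = TRUE) {
  paired <- pair_models(a, b)
  sup <- superpose(paired)
  disp <- displacement_field(paired, superpose_first = superpose_first)
  ddm <- distance_difference_matrix(paired)
  out <- list(n_pairs = nrow(paired$keys),
              rmsd = sup$rmsd,
              mean_displacement = mean(disp$length),
              rg_a = radius_of_gyration(a), rg_b = radius_of_gyration(b),
              per_residue_compaction = ddm$per_residue_sum,
              total_relative_change = sum(ddm$per_residue_sum) / 2,
              net_compaction = sum(ddm$per_residue_sum) < 0,
              displacement = disp)
  if (!is.null(ensemble)) {
    err <- sqrt(rowMeans(ensemble$sd^2))      # per-atom coordinate error
    out$coordinate_error <- err
    out$n_exceeding_2sigma <- sum(disp$length > 2 * err)
    out$mean_coordinate_error <- mean(err)
  }
  class(out) <- "structure_comparison"
  out
}

#' @export
print.structure_comparison <- function(x, ...) {
  cat(sprintf("structure_comparison: %d paired residues\n", x$n_pairs))
  cat(sprintf("  RMSD %.3f A, mean displacement %.3f A\n", x$rmsd,
              x$mean_displacement))
  cat(sprintf("  Rg %.2f -> %.2f A (ratio %.4f); net %s\n", x$rg_a,
              x$rg_b, x$rg_b / x$rg_a,
              if (x$net_compaction) "compaction" else "expansion"))
  if (!is.null(x$n_exceeding_2sigma))
    cat(sprintf("  %d residues displaced beyond 2x bootstrap error (mean %.3f A)\n",
                x$n_exceeding_2sigma, x$mean_coordinate_error))
  invisible(x)
}
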