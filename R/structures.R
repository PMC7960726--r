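# Atomic model container and PDB I/O (via bio3d), plus a synthetic
# haemoglobin-like reference model for ground-truth structural tests.

#' Atomic structure model
#'
#' A light S3 container for an atomic model: an atom table with chain,
#' residue number/name, atom name, coordinates (Angstrom), B factor and
#' occupancy, plus optional cell metadata. `(chain, resno, elety)` keys
#' must be unique and coordinates finite.
#'
#' @param atoms data frame with columns chain, resno, resid, elety, x, y,
#'   z, b, o.
#' @param cell optional cell edges, Angstrom.
#' @param space_group optional space-group symbol.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, cell = NULL, space_group = NULL) {
  req <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  stopifnot(is.data.frame(atoms), all(req %in% names(atoms)))
  if (nrow(atoms) == 0L) stop("empty atom table", call. = FALSE)
  if (!all(is.finite(as.matrix(atoms[c("x", "y", "z")]))))
    stop("non-finite coordinates", call. = FALSE)
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate (chain, resno, atom) keys", call. = FALSE)
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$o)) atoms$o <- 1
  structure(list(atoms = atoms, cell = cell, space_group = space_group),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms, %d residues, chains %s\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno))),
              paste(unique(x$atoms$chain), collapse = "")))
  invisible(x)
}

#' Read a structure model from a PDB file
#'
#' @param path PDB file path.
#' @return a [structure_model()].
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  structure_model(data.frame(chain = a$chain, resno = a$resno,
                             resid = a$resid, elety = a$elety,
                             x = a$x, y = a$y, z = a$z,
                             b = a$b, o = a$o,
                             stringsAsFactors = FALSE))
}

#' Write a structure model to a PDB file
#'
#' @param model a [structure_model()].
#' @param path output path.
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[c("x", "y", "z")]))),
                   resno = a$resno, chain = a$chain, resid = a$resid,
                   elety = a$elety, b = a$b, o = a$o)
  invisible(path)
}

# C-alpha subset (synthetic models are CA-only already).
ca_atoms <- function(model) {
  a <- model$atoms
  a[a$elety == "CA", , drop = FALSE]
}

#' Synthetic haemoglobin-like tetramer (C-alpha trace)
#'
#' A compact four-chain model emulating the alpha2/beta2 tetramer used in
#' the experiments: chains A/C of 141 residues and B/D of 146 residues
#' (574 total), each built as a bent helical C-alpha curve, arranged
#' around a central channel. This is a synthetic stand-in with realistic
#' size and packing, not a deposited structure.
#'
#' @param n_res_alpha,n_res_beta residues per alpha-like and beta-like
#'   chain.
#' @return a [structure_model()] with one CA atom per residue.
#' @export
synthetic_globin_model <- function(n_res_alpha = 141, n_res_beta = 146) {
  build_chain <- function(n, centre, phase) {
    t <- seq_len(n)
    # helical trace (rise 1.5 A, ~100 deg/residue) folded by slow bends
    r <- 8 + 3 * sin(2 * pi * t / n + phase)
    x <- r * cos(t * 100 * pi / 180) + 6 * sin(2 * pi * t / 70 + phase)
    y <- r * sin(t * 100 * pi / 180) + 6 * cos(2 * pi * t / 55 + phase)
    z <- 1.5 * t - 0.75 * n + 5 * sin(2 * pi * t / 45 + 2 * phase)
    cbind(x, y, z) * 0.55 + matrix(centre, n, 3, byrow = TRUE)
  }
  chains <- list(A = n_res_alpha, B = n_res_beta,
                 C = n_res_alpha, D = n_res_beta)
  centres <- list(A = c(14, 14, 0), B = c(-14, 14, 2),
                  C = c(-14, -14, 0), D = c(14, -14, -2))
  rows <- lapply(names(chains), function(ch) {
    n <- chains[[ch]]
    xyz <- build_chain(n, centres[[ch]], phase = match(ch, names(chains)))
    data.frame(chain = ch, resno = seq_len(n), resid = "ALA",
               elety = "CA", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               b = 30, o = 1, stringsAsFactors = FALSE)
  })
  structure_model(do.call(rbind, rows))
}

#' Perturb a reference model with a correlated field plus compaction
#'
#' Builds the second member of a structure pair: the reference is scaled
#' about its centroid by `compaction`, then displaced by a smooth,
#' sequence-correlated vector field (low-frequency sinusoids per chain,
#' random phases, rescaled to an exact root-mean-square displacement and
#' centred so it carries no net translation). Per-image coordinate
#' observations (perturbed coordinates plus i.i.d. Gaussian noise) are
#' returned for bootstrap testing.
#'
#' @param reference a [structure_model()] (non-empty).
#' @param displacement_spec list with `amplitude` (RMS displacement per
#'   atom, Angstrom; 0 for none) and `wavelength` (residues).
#' @param compaction uniform scale factor about the centroid, in
#'   (0.9, 1.1).
#' @param noise_sd per-image, per-coordinate observation noise SD,
#'   Angstrom.
#' @param n_images number of per-image observations.
#' @param seed RNG seed.
#' @return list with `model` (perturbed [structure_model()]),
#'   `observations` (n_atoms x 3 x n_images array, image ids in
#'   dimnames), and `truth` (planted field, compaction, noise SD).
#' @export
generate_structure_pair <- function(reference,
                                    displacement_spec =
                                      list(amplitude = 0.11,
                                           wavelength = 25),
                                    compaction = 1.0, noise_sd = 0.1,
                                    n_images = 50, seed = 1) {
  stopifnot(inherits(reference, "structure_model"))
  if (compaction <= 0.9 || compaction >= 1.1)
    stop("'compaction' must lie in (0.9, 1.1)", call. = FALSE)
  a <- reference$atoms
  xyz <- as.matrix(a[c("x", "y", "z")])
  n <- nrow(xyz)
  amp <- displacement_spec$amplitude %||% 0
  wav <- displacement_spec$wavelength %||% 25

  field <- matrix(0, n, 3)
  if (amp > 0) {
    field <- with_seed(substream_seed(seed, "field"), {
      f <- matrix(0, n, 3)
      for (ch in unique(a$chain)) {
        sel <- which(a$chain == ch)
        i <- seq_along(sel)
        ph <- stats::runif(3, 0, 2 * pi)
        for (c3 in 1:3)
          f[sel, c3] <- sin(2 * pi * i / wav + ph[c3])
      }
      f <- sweep(f, 2, colMeans(f))          # no net translation
      f * amp / sqrt(mean(rowSums(f^2)))     # exact RMS = amplitude
    })
  }

  centroid <- colMeans(xyz)
  xyz_b <- sweep(sweep(xyz, 2, centroid), 2, rep(compaction, 3), `*`)
  xyz_b <- sweep(xyz_b, 2, centroid, `+`) + field

  b_atoms <- a
  b_atoms[c("x", "y", "z")] <- xyz_b
  model_b <- structure_model(b_atoms)

  obs <- with_seed(substream_seed(seed, "obs"), {
    arr <- array(rep(xyz_b, n_images), dim = c(n, 3, n_images))
    if (noise_sd > 0)
      arr <- arr + array(stats::rnorm(n * 3 * n_images, 0, noise_sd),
                         dim = c(n, 3, n_images))
    dimnames(arr) <- list(NULL, c("x", "y", "z"),
                          paste0("img", seq_len(n_images)))
    arr
  })

  list(model = model_b, observations = obs,
       truth = list(displacement_field = field, compaction = compaction,
                    noise_sd = noise_sd))
}
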