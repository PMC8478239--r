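#' Generate a toy structure with a declared contact set
#'
#' Builds PDB text for a synthetic chain whose residues are clusters of
#' five heavy atoms placed so that, under the `"methods"` contact preset
#' (at least 5 atom pairs within 4.5 angstroms, sequence separation >= 2),
#' the computed contact map is exactly the declared one: contacting
#' residue pairs have cluster centres 3 angstroms apart (all 25 atom pairs
#' qualify) and all other pairs are at least 15 angstroms apart (no pair
#' qualifies). No physics is implied; only inter-residue distances matter.
#'
#' Geometries: `"extended"` — a straight chain, no contacts; `"hairpin"` —
#' the chain folds back so residue `i` contacts residue `n + 1 - i`
#' (apex pairs closer than the sequence-separation minimum are not
#' declared); `"nested-loops"` — three nested contacts
#' `(1, n), (3, n-2), (5, n-4)`, giving residue 5 a purely inverse-parallel
#' neighbourhood.
#'
#' @param n_residues chain length (>= 3; `"hairpin"` needs >= 4,
#'   `"nested-loops"` needs >= 11).
#' @param geometry `"extended"`, `"hairpin"` or `"nested-loops"`.
#' @param seed RNG seed for the small coordinate jitter (default 1);
#'   output is byte-identical for identical seeds.
#' @return list with `pdb_text` (character vector of PDB lines),
#'   `contacts` (data.frame `i`, `j` of declared contacts) and
#'   `structure` (the [ProteinStructure-class] itself).
#' @export
makeStructure <- function(n_residues,
                          geometry = c("extended", "hairpin",
                                       "nested-loops"),
                          seed = 1L) {
  geometry <- match.arg(geometry)
  n <- as.integer(n_residues)
  if (n < 3) stop("need n_residues >= 3")

  centers <- matrix(0, n, 3)
  expected <- data.frame(i = integer(), j = integer())
  if (geometry == "extended") {
    centers[, 1] <- 20 * seq_len(n)
  } else if (geometry == "hairpin") {
    if (n < 4) stop("hairpin needs n_residues >= 4")
    half <- n %/% 2
    for (r in seq_len(n)) {
      if (r <= half) {
        centers[r, ] <- c(15 * r, 0, 0)
      } else if (n %% 2 == 1 && r == half + 1) {
        centers[r, ] <- c(15 * r, 1.5, 20)  # odd apex, kept out of contact
      } else {
        centers[r, ] <- c(15 * (n + 1 - r), 3, 0)
      }
    }
    pairs <- cbind(seq_len(half), n + 1 - seq_len(half))
    pairs <- pairs[pairs[, 2] - pairs[, 1] >= 2, , drop = FALSE]
    expected <- data.frame(i = pairs[, 1], j = pairs[, 2])
  } else {
    if (n < 11) stop("nested-loops needs n_residues >= 11")
    pairs <- cbind(c(1L, 3L, 5L), c(n, n - 2L, n - 4L))
    far <- setdiff(seq_len(n), as.vector(pairs))
    for (k in seq_len(nrow(pairs))) {
      centers[pairs[k, 1], ] <- c(0, 40 * k, 0)
      centers[pairs[k, 2], ] <- c(3, 40 * k, 0)
    }
    centers[far, ] <- cbind(200 + 20 * seq_along(far), -200, 0)
    expected <- data.frame(i = pairs[, 1], j = pairs[, 2])
  }

  set.seed(as.integer(seed))
  offs <- rbind(c(0, 0, 0), c(0.5, 0, 0), c(-0.5, 0, 0),
                c(0, 0.5, 0), c(0, -0.5, 0))
  atom_names <- c("CA", "CB", "CG", "CD", "CE")
  rows <- vector("list", n * 5)
  for (r in seq_len(n)) {
    jit <- matrix(stats::runif(15, -0.05, 0.05), 5, 3)
    xyz <- sweep(offs + jit, 2, centers[r, ], "+")
    for (a in 1:5) {
      rows[[(r - 1) * 5 + a]] <- data.frame(
        type = "ATOM", eleno = (r - 1) * 5 + a, elety = atom_names[a],
        resid = AA3[(r - 1) %% 20 + 1], chain = "A", resno = r,
        insert = "", x = round(xyz[a, 1], 3), y = round(xyz[a, 2], 3),
        z = round(xyz[a, 3], 3), o = 1, b = 10 + (r %% 10),
        elesy = "C", is_heavy = TRUE)
    }
  }
  atoms <- do.call(rbind, rows)
  struct <- new("ProteinStructure", atoms = atoms, source = "<synthetic>")
  list(pdb_text = writePDB(struct), contacts = expected,
       structure = struct)
}

#' Generate random contact maps with brute-force relation tables
#'
#' Samples duplicate-free interval sets uniformly from the admissible
#' `(i, j)` pairs (`j - i >= 2`) of a chain and pairs each map with its
#' exhaustive relation table — oracle fixtures for the topology module.
#'
#' @param n_maps number of maps.
#' @param n_contacts_max maximal contacts per map (size drawn uniformly
#'   from 0..max).
#' @param seed RNG seed.
#' @param n_residues chain length the intervals are drawn from.
#' @return list of `n_maps` elements, each a list with `cmap`
#'   (a [ContactMap-class]) and `relations` (from
#'   [bruteForceRelations()]).
#' @export
makeContactMaps <- function(n_maps, n_contacts_max = 12L, seed = 1L,
                            n_residues = 30L) {
  if (n_contacts_max > 100L) stop("n_contacts_max exceeds the oracle limit")
  set.seed(as.integer(seed))
  all_pairs <- which(upper.tri(matrix(TRUE, n_residues, n_residues)),
                     arr.ind = TRUE)
  all_pairs <- all_pairs[all_pairs[, 2] - all_pairs[, 1] >= 2, , drop = FALSE]
  lapply(seq_len(n_maps), function(m) {
    nc <- sample(0:n_contacts_max, 1)
    sel <- if (nc == 0) integer(0) else sample(nrow(all_pairs), nc)
    cmap <- contactMapFromIntervals(
      data.frame(i = all_pairs[sel, 1], j = all_pairs[sel, 2]))
    list(cmap = cmap, relations = bruteForceRelations(cmap))
  })
}

#' Generate a labelled synthetic variant table
#'
#' Draws per-variant features and responsiveness labels from a stated
#' generative model: `ddg ~ Normal(1, 1.5)` (most pathogenic variants
#' destabilize), `binds_ligand ~ Bernoulli(0.1)`,
#' `p_inv ~ round(Gamma(shape 2, scale 60))`, and
#' `responsive ~ Bernoulli(plogis(eta + noise))` with linear predictor
#' `eta = b0 + b_ddg * ddg + b_lig * binds_ligand + b_pinv * p_inv` and
#' optional Gaussian noise on the logit scale. The default coefficients
#' make destabilization, ligand contact and a high inverse-parallel count
#' all reduce the rescue probability, so non-responsive variants have
#' higher mean `ddg` than responsive ones. The generator settings are
#' attached as the `"generator"` attribute for recovery tests.
#'
#' @param n_variants number of rows.
#' @param coef named numeric `c(intercept, ddg, binds_ligand, p_inv)` of
#'   the logistic model.
#' @param noise_sd standard deviation of logit-scale noise (default 0).
#' @param seed RNG seed.
#' @return data.frame with columns `variant`, `wt_aa`, `position`,
#'   `mut_aa`, `ddg`, `binds_ligand`, `p_inv`, `responsive`.
#' @export
makeVariantTable <- function(n_variants = 2000L,
                             coef = c(intercept = 0.5, ddg = -1.2,
                                      binds_ligand = -2.0, p_inv = -0.01),
                             noise_sd = 0, seed = 1L) {
  stopifnot(all(c("intercept", "ddg", "binds_ligand", "p_inv")
                %in% names(coef)))
  set.seed(as.integer(seed))
  n <- as.integer(n_variants)
  ddg <- stats::rnorm(n, mean = 1.0, sd = 1.5)
  binds <- stats::rbinom(n, 1, 0.1) == 1
  p_inv <- as.integer(round(stats::rgamma(n, shape = 2, scale = 60)))
  eta <- coef[["intercept"]] + coef[["ddg"]] * ddg +
    coef[["binds_ligand"]] * binds + coef[["p_inv"]] * p_inv
  if (noise_sd > 0) eta <- eta + stats::rnorm(n, 0, noise_sd)
  responsive <- stats::rbinom(n, 1, stats::plogis(eta)) == 1
  wt <- sample(AA1, n, replace = TRUE)
  mut <- vapply(wt, function(w) sample(setdiff(AA1, w), 1), "")
  pos <- sample.int(500L, n, replace = TRUE)
  out <- data.frame(variant = paste0(wt, pos, mut), wt_aa = wt,
                    position = pos, mut_aa = unname(mut), ddg = ddg,
                    binds_ligand = binds, p_inv = p_inv,
                    responsive = responsive)
  attr(out, "generator") <- list(coef = coef, noise_sd = noise_sd,
                                 seed = as.integer(seed))
  out
}
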