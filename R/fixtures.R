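# Synthetic structures and score tables with analytically known LBI/PBI,
# Spearman, eROCE and enrichment-factor values. These stand in for
# benchmark-style inputs so the whole pipeline is testable offline; they
# make no attempt at physically realistic protein geometry.

# deterministic quasi-uniform directions on the unit sphere (Fibonacci)
.sphere_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.expand_bf <- function(bf, n, what) {
  if (length(bf) == 1L) return(rep(bf, n))
  if (length(bf) != n) {
    stop(sprintf("%s B-factors must be length 1 or %d", what, n),
         call. = FALSE)
  }
  bf
}

# run fn with a locally seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  fn()
}

#' Build a synthetic protein-ligand complex with known B-factor indices
#'
#' Places a hetero ligand residue on a tiny shell around the origin and
#' protein CA atoms on two spherical shells: an inner "site" shell whose
#' atoms fall inside any binding-site radius between the shells, and an
#' outer "far" shell whose atoms fall outside. For any such radius the site
#' membership — and therefore all three medians, LBI and PBI — is known in
#' closed form from the supplied B-factor assignments.
#'
#' Protein atoms are emitted as CA-only glycine records; the index
#' computation never inspects residue chemistry. Coordinates are
#' deterministic; a small positional jitter is applied only when `seed` is
#' given.
#'
#' @param n_ligand,n_site,n_far atom counts (each >= 1).
#' @param bf_ligand,bf_site,bf_far B-factor assignment for each pool: a
#'   single constant or a vector of per-atom values.
#' @param inner_max maximum distance (Angstrom) of site atoms from the
#'   origin; must be below `outer_min`.
#' @param outer_min minimum distance of far atoms from the origin.
#' @param seed optional integer; adds jitter within the shell margins.
#' @param pdb_id identifier stamped on the model.
#' @return a `pdb_structure` with an `"expected"` attribute: list with
#'   `bf_l`, `bf_bs`, `bf_p`, `lbi`, `pbi` valid for any radius in
#'   `(inner_max, outer_min)`.
#' @export
make_synthetic_complex <- function(n_ligand = 10L, n_site = 20L, n_far = 40L,
                                   bf_ligand = 40, bf_site = 20, bf_far = 10,
                                   inner_max = 4, outer_min = 25,
                                   seed = NULL, pdb_id = "synth") {
  stopifnot(n_ligand >= 1L, n_site >= 1L, n_far >= 1L)
  if (inner_max >= outer_min) {
    stop("inner shell must end before the outer shell begins", call. = FALSE)
  }
  bf_ligand <- .expand_bf(bf_ligand, n_ligand, "ligand")
  bf_site <- .expand_bf(bf_site, n_site, "site")
  bf_far <- .expand_bf(bf_far, n_far, "far")

  lig_eps <- min(0.3, inner_max / 10)
  # site atoms strictly inside inner_max even after the ligand offset
  r_site <- seq(max(1.2, inner_max / 2), inner_max - lig_eps,
                length.out = n_site)
  r_far <- seq(outer_min + lig_eps, outer_min + 5, length.out = n_far)

  jitter_site <- jitter_far <- 0
  if (!is.null(seed)) {
    jit <- .with_seed(seed, function() {
      list(site = stats::runif(n_site, -0.05, 0.05),
           far = stats::runif(n_far, 0, 2))
    })
    jitter_site <- jit$site
    jitter_far <- jit$far
  }
  r_site <- pmin(pmax(r_site + jitter_site, 0.8), inner_max - lig_eps)
  r_far <- r_far + jitter_far

  lig_xyz <- .sphere_directions(n_ligand) * lig_eps
  site_xyz <- .sphere_directions(n_site) * r_site
  far_xyz <- .sphere_directions(n_far) * r_far

  n_prot <- n_site + n_far
  prot_xyz <- rbind(site_xyz, far_xyz)
  atoms <- data.frame(
    serial = seq_len(n_prot + n_ligand),
    name = c(rep("CA", n_prot), sprintf("C%d", seq_len(n_ligand))),
    element = "C",
    altloc = "",
    resname = c(rep("GLY", n_prot), rep("LIG", n_ligand)),
    chain = "A",
    resseq = c(seq_len(n_prot), rep(900L, n_ligand)),
    icode = "",
    x = c(prot_xyz[, 1], lig_xyz[, 1]),
    y = c(prot_xyz[, 2], lig_xyz[, 2]),
    z = c(prot_xyz[, 3], lig_xyz[, 3]),
    occupancy = 1,
    bfactor = c(bf_site, bf_far, bf_ligand),
    is_hetero = c(rep(FALSE, n_prot), rep(TRUE, n_ligand)),
    stringsAsFactors = FALSE
  )

  expected <- list(
    bf_l = stats::median(bf_ligand),
    bf_bs = stats::median(bf_site),
    bf_p = stats::median(c(bf_site, bf_far))
  )
  expected$lbi <- if (expected$bf_l > 0) expected$bf_bs / expected$bf_l
                  else NA_real_
  expected$pbi <- if (expected$bf_p > 0) expected$bf_bs / expected$bf_p
                  else NA_real_

  structure(
    structure(
      list(pdb_id = pdb_id, atoms = atoms, resolution = NA_real_,
           r_work = NA_real_, r_free = NA_real_,
           method = "SYNTHETIC",
           n_nonpositive_b = sum(atoms$bfactor <= 0)),
      class = "pdb_structure"
    ),
    expected = expected
  )
}

#' Build an affinity/metric table with a known rank relationship
#'
#' Generates pBA values spread over \[2, 14\] together with a metric linked
#' monotonically ("monotone" gives population Spearman rho = 1,
#' "anti" gives -1) or with additive Gaussian noise ("noisy"); the full-set
#' Spearman of a noisy table is computable directly for validation of the
#' resampling machinery.
#'
#' @param n number of complexes (>= 10).
#' @param link one of "monotone", "anti", "noisy".
#' @param noise_sd Gaussian noise SD for the "noisy" link (pBA log units).
#' @param seed optional integer seed for the noise.
#' @return list with `records` (data frame: `pdb_id`, `target_id`, `pba`)
#'   and `metric` (named numeric vector, one value per `pdb_id`).
#' @export
make_ranking_dataset <- function(n = 285L,
                                 link = c("monotone", "anti", "noisy"),
                                 noise_sd = 1, seed = NULL) {
  stopifnot(n >= 10L)
  link <- match.arg(link)
  pba <- seq(2, 14, length.out = n)
  ids <- sprintf("syn%04d", seq_len(n))
  metric <- switch(
    link,
    monotone = sqrt(pba),     # any strictly increasing transform
    anti = -pba,
    noisy = {
      noise <- if (is.null(seed)) stats::rnorm(n, 0, noise_sd)
               else .with_seed(seed, function() stats::rnorm(n, 0, noise_sd))
      pba + noise
    }
  )
  names(metric) <- ids
  list(
    records = data.frame(pdb_id = ids,
                         target_id = sprintf("t%03d", (seq_len(n) - 1L) %/% 5L + 1L),
                         pba = pba, stringsAsFactors = FALSE),
    metric = metric
  )
}

#' Build a labelled screening ranking with known enrichment values
#'
#' @param n_actives,n_decoys counts (each >= 1).
#' @param placement where the actives sit in the ranked list:
#'   "first" (all actives on top: eROCE = 1), "random" (uniform shuffle:
#'   expected EF = 1), or "fpr" (all actives placed immediately after a
#'   fraction `fpr` of the decoys, so every active has exactly that false
#'   positive rate).
#' @param fpr false positive rate for the "fpr" placement; `fpr * n_decoys`
#'   must be a whole number for the rate to be exact.
#' @param seed optional seed for the "random" placement.
#' @return logical vector in rank order (`TRUE` = active).
#' @export
make_screening_dataset <- function(n_actives, n_decoys,
                                   placement = c("first", "random", "fpr"),
                                   fpr = 0.05, seed = NULL) {
  stopifnot(n_actives >= 1L, n_decoys >= 1L)
  placement <- match.arg(placement)
  switch(
    placement,
    first = c(rep(TRUE, n_actives), rep(FALSE, n_decoys)),
    random = {
      lab <- c(rep(TRUE, n_actives), rep(FALSE, n_decoys))
      if (is.null(seed)) sample(lab)
      else .with_seed(seed, function() sample(lab))
    },
    fpr = {
      k <- round(fpr * n_decoys)
      c(rep(FALSE, k), rep(TRUE, n_actives), rep(FALSE, n_decoys - k))
    }
  )
}
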