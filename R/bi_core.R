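# Binding-site extraction by radius around the bound ligand, and the two
# median-based B-factor indices:
#
#   LBI = BF_BS / BF_L    PBI = BF_BS / BF_P
#
# where BF_BS, BF_L and BF_P are the median atomic B-factors of the binding
# site, the ligand and the protein. Medians rather than means, because
# deposited atomic B-factors — particularly of small-molecule ligands —
# frequently carry outliers.

#' Median atomic B-factor
#'
#' @param atoms an atom data frame / selection, or a bare numeric vector of
#'   B-factors.
#' @return the median (Angstrom^2): the middle order statistic for odd n,
#'   the mean of the two central order statistics for even n.
#' @export
median_bfactor <- function(atoms) {
  b <- if (is.numeric(atoms)) atoms else .atoms_of(atoms)$bfactor
  if (!length(b)) stop("no atoms for median", call. = FALSE)
  stats::median(b)
}

# squared distance from each row of P (n x 3) to its nearest row of L (m x 3)
.min_sq_dist <- function(P, L) {
  p2 <- rowSums(P * P)
  l2 <- rowSums(L * L)
  cross <- P %*% t(L)
  d2 <- outer(p2, l2, "+") - 2 * cross
  d2[d2 < 0] <- 0  # guard against negative rounding residue
  apply(d2, 1L, min)
}

.coords <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

.protein_heavy <- function(model, chains = NULL) {
  atoms <- .atoms_of(model)
  atoms <- atoms[.is_protein_atom(atoms), , drop = FALSE]
  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  if (!is.null(chains)) atoms <- atoms[atoms$chain %in% chains, , drop = FALSE]
  rownames(atoms) <- NULL
  atoms
}

#' Extract the binding site at a radius around the ligand
#'
#' The binding site is the set of protein heavy atoms (of the selected
#' chains) whose minimum Euclidean distance to any ligand heavy atom is at
#' most `radius` (closed boundary). Waters, ions and other hetero groups are
#' never part of the site.
#'
#' @param model a `pdb_structure`.
#' @param ligand a `ligand_selection` from [select_ligand()], or an atom
#'   data frame of ligand heavy atoms.
#' @param radius site radius in Angstrom (> 0).
#' @param chains optional character vector restricting the protein chains
#'   considered; default all chains.
#' @return object of class `binding_site`: list with `radius`, `atoms`, and
#'   `warnings` (contains `"empty binding site"` when no atom qualifies).
#' @export
extract_binding_site <- function(model, ligand, radius, chains = NULL) {
  stopifnot(is.numeric(radius), length(radius) == 1L, radius > 0)
  lig_atoms <- heavy_atoms(.atoms_of(ligand))
  if (!nrow(lig_atoms)) stop("ligand selection is empty", call. = FALSE)
  prot <- .protein_heavy(model, chains)
  warnings <- character()
  if (nrow(prot)) {
    d2 <- .min_sq_dist(.coords(prot), .coords(lig_atoms))
    site <- prot[d2 <= radius^2, , drop = FALSE]
  } else {
    site <- prot
  }
  rownames(site) <- NULL
  if (!nrow(site)) warnings <- c(warnings, "empty binding site")
  structure(list(radius = radius, atoms = site, warnings = warnings),
            class = "binding_site")
}

#' Compute the ligand and protein B-factor indices at one radius
#'
#' LBI is the ratio of the median binding-site B-factor to the median ligand
#' B-factor; PBI the ratio of the median binding-site B-factor to the median
#' protein B-factor (protein restricted to `chains` when given). Indices
#' whose denominator is not positive, or whose binding site is empty, are
#' reported as `NA` with a machine-readable reason — never as 0 or Inf.
#'
#' @inheritParams extract_binding_site
#' @param radius site radius in Angstrom; the conventional default is 10.
#' @return object of class `bi_result` with medians `bf_bs`, `bf_l`, `bf_p`,
#'   indices `lbi`, `pbi` (with `lbi_reason` / `pbi_reason` when undefined),
#'   atom counts `n_site`, `n_ligand`, `n_protein`, structure metadata, and
#'   quality `warnings`.
#' @examples
#' cx <- make_synthetic_complex(bf_ligand = 40, bf_site = 20, bf_far = 10)
#' lig <- select_ligand(cx, "A", "LIG")
#' compute_bi(cx, lig, radius = 10)
#' @export
compute_bi <- function(model, ligand, radius = 10, chains = NULL) {
  lig_atoms <- heavy_atoms(.atoms_of(ligand))
  if (!nrow(lig_atoms)) stop("ligand has no heavy atoms", call. = FALSE)
  prot <- .protein_heavy(model, chains)
  if (!nrow(prot)) stop("model has no protein heavy atoms", call. = FALSE)

  site <- extract_binding_site(model, ligand, radius, chains)
  warnings <- site$warnings

  bf_l <- median_bfactor(lig_atoms)
  bf_p <- median_bfactor(prot)
  bf_bs <- if (nrow(site$atoms)) median_bfactor(site$atoms) else NA_real_

  pools <- c(site = nrow(site$atoms), ligand = nrow(lig_atoms),
             protein = nrow(prot))
  small <- pools[pools > 0 & pools < 5]
  if (length(small)) {
    warnings <- c(warnings, sprintf("small atom pool: %s (n=%d)",
                                    names(small), small))
  }
  for (nm in c(bs = bf_bs, l = bf_l, p = bf_p)[!is.na(c(bf_bs, bf_l, bf_p))]) {
    if (nm <= 0) {
      warnings <- c(warnings, "median B-factor <= 0")
      break
    }
  }
  if (inherits(model, "pdb_structure") && model$n_nonpositive_b > 0) {
    warnings <- c(warnings,
                  sprintf("%d deposited B-factor(s) <= 0", model$n_nonpositive_b))
  }

  lbi <- pbi <- NA_real_
  lbi_reason <- pbi_reason <- NA_character_
  if (is.na(bf_bs)) {
    lbi_reason <- pbi_reason <- "empty binding site"
  } else {
    if (bf_l > 0) lbi <- bf_bs / bf_l else lbi_reason <- "ligand median B <= 0"
    if (bf_p > 0) pbi <- bf_bs / bf_p else pbi_reason <- "protein median B <= 0"
  }

  meta <- if (inherits(model, "pdb_structure")) {
    model[c("pdb_id", "resolution", "r_work", "r_free")]
  } else {
    list(pdb_id = "unknown", resolution = NA_real_, r_work = NA_real_,
         r_free = NA_real_)
  }
  lig_label <- if (inherits(ligand, "ligand_selection")) {
    sprintf("%s:%s:%s", ligand$chain, ligand$resname,
            as.character(ligand$resseq))
  } else "custom"

  structure(
    list(
      pdb_id = meta$pdb_id,
      chains = if (is.null(chains)) "all" else paste(chains, collapse = ","),
      ligand = lig_label,
      radius = radius,
      bf_bs = bf_bs, bf_l = bf_l, bf_p = bf_p,
      lbi = lbi, pbi = pbi,
      lbi_reason = lbi_reason, pbi_reason = pbi_reason,
      n_site = nrow(site$atoms), n_ligand = nrow(lig_atoms),
      n_protein = nrow(prot),
      resolution = meta$resolution, r_work = meta$r_work,
      r_free = meta$r_free,
      warnings = warnings
    ),
    class = "bi_result"
  )
}

#' B-factor index profile over several radii
#'
#' @inheritParams compute_bi
#' @param radii vector of positive radii in Angstrom; the benchmark
#'   convention is 5, 10, 15 and 20.
#' @return object of class `bi_profile`: a list of `bi_result`, one per
#'   radius. `as.data.frame()` flattens it to the tabular output layout.
#' @export
bi_profile <- function(model, ligand, radii = c(5, 10, 15, 20),
                       chains = NULL) {
  stopifnot(length(radii) >= 1L, all(radii > 0))
  res <- lapply(radii, function(r) compute_bi(model, ligand, r, chains))
  structure(res, class = "bi_profile")
}

#' @export
as.data.frame.bi_result <- function(x, ...) {
  data.frame(
    pdb_id = x$pdb_id, chains = x$chains, ligand = x$ligand,
    radius = x$radius,
    n_ligand = x$n_ligand, n_site = x$n_site, n_protein = x$n_protein,
    bf_l = x$bf_l, bf_bs = x$bf_bs, bf_p = x$bf_p,
    lbi = x$lbi, pbi = x$pbi,
    resolution = x$resolution, r_work = x$r_work, r_free = x$r_free,
    warnings = paste(x$warnings, collapse = "; "),
    stringsAsFactors = FALSE
  )
}

#' @export
as.data.frame.bi_profile <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), as.data.frame))
}

#' @export
print.bi_result <- function(x, digits = 3, ...) {
  cat(sprintf("<bi_result> %s  ligand %s  chains %s  radius %g A\n",
              x$pdb_id, x$ligand, x$chains, x$radius))
  cat(sprintf("  BF_BS = %s  BF_L = %s  BF_P = %s (medians, A^2)\n",
              format(x$bf_bs, digits = digits),
              format(x$bf_l, digits = digits),
              format(x$bf_p, digits = digits)))
  lbi_txt <- if (is.na(x$lbi)) paste0("undefined (", x$lbi_reason, ")")
             else format(x$lbi, digits = digits)
  pbi_txt <- if (is.na(x$pbi)) paste0("undefined (", x$pbi_reason, ")")
             else format(x$pbi, digits = digits)
  cat(sprintf("  LBI = %s   PBI = %s\n", lbi_txt, pbi_txt))
  cat(sprintf("  atoms: site %d, ligand %d, protein %d\n",
              x$n_site, x$n_ligand, x$n_protein))
  if (length(x$warnings)) {
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
print.bi_profile <- function(x, ...) {
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
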