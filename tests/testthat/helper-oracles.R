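# Independent brute-force oracles and tiny PDB-text builders used across
# the suite. Oracles deliberately avoid the package's own code paths.

# one ATOM/HETATM line in PDB fixed columns
pdb_line <- function(record = "ATOM", serial = 1, name = "CA", altloc = "",
                     resname = "GLY", chain = "A", resseq = 1, icode = "",
                     x = 0, y = 0, z = 0, occ = 1, b = 20, element = "C") {
  name_fmt <- if (nchar(name) >= 4) substr(name, 1, 4) else
    if (nchar(element) == 1) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_fmt,
          ifelse(nzchar(altloc), altloc, " "), resname, chain, resseq,
          ifelse(nzchar(icode), icode, " "), x, y, z, occ, b, element)
}

# sort-based median, independent of stats::median
oracle_median <- function(v) {
  s <- sort(v)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# all-pairs-distance brute-force B-factor indices
oracle_bi <- function(model, ligand, radius, chains = NULL) {
  atoms <- model$atoms
  hv <- !(atoms$element %in% c("H", "D"))
  prot_std <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
                "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL",
                "MSE")
  is_prot <- (!atoms$is_hetero | atoms$resname %in% prot_std) & hv
  if (!is.null(chains)) is_prot <- is_prot & atoms$chain %in% chains
  lig <- ligand$atoms
  lig <- lig[!(lig$element %in% c("H", "D")), , drop = FALSE]
  pidx <- which(is_prot)
  in_site <- logical(length(pidx))
  for (k in seq_along(pidx)) {
    i <- pidx[k]
    dmin <- Inf
    for (j in seq_len(nrow(lig))) {
      d <- sqrt((atoms$x[i] - lig$x[j])^2 + (atoms$y[i] - lig$y[j])^2 +
                  (atoms$z[i] - lig$z[j])^2)
      if (d < dmin) dmin <- d
    }
    in_site[k] <- dmin <= radius
  }
  bf_bs <- if (any(in_site)) oracle_median(atoms$bfactor[pidx[in_site]]) else NA
  bf_l <- oracle_median(lig$bfactor)
  bf_p <- oracle_median(atoms$bfactor[pidx])
  list(bf_bs = bf_bs, bf_l = bf_l, bf_p = bf_p,
       lbi = bf_bs / bf_l, pbi = bf_bs / bf_p,
       n_site = sum(in_site))
}

# the classic closed form, valid on tie-free data
oracle_spearman_eq3 <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# rank-then-Pearson, independent of cor(method = "spearman")
oracle_spearman_pearson <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# per-active enumeration of the exponential enrichment weight
oracle_eroce <- function(labels, alpha = 32.19) {
  lab <- as.logical(labels)
  nd <- sum(!lab)
  w <- c()
  for (i in which(lab)) {
    fpr <- sum(!lab[seq_len(i - 1)]) / nd
    w <- c(w, exp(-alpha * fpr))
  }
  mean(w)
}

oracle_ef <- function(labels, fraction) {
  lab <- as.logical(labels)
  top <- ceiling(fraction * length(lab))
  sum(lab[seq_len(top)]) / (sum(lab) * fraction)
}

# a random small complex fixture with varied B-factors; expected values
# carried by make_synthetic_complex's closed form
random_complex <- function(seed) {
  set.seed(seed)
  make_synthetic_complex(
    n_ligand = sample(3:12, 1), n_site = sample(5:20, 1),
    n_far = sample(5:25, 1),
    bf_ligand = round(runif(1, 5, 80), 2),
    bf_site = round(runif(1, 5, 80), 2),
    bf_far = round(runif(1, 5, 80), 2),
    seed = seed
  )
}
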