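# PDB fixed-column reader/writer exposing exactly the atom set the B-factor
# indices are defined on: first model, first alternate-location configuration,
# heavy atoms, plus the header metadata (resolution, R, R-free) used when
# comparing structure-quality metrics.

.WATER_RESNAMES <- c("HOH", "WAT", "DOD", "D2O")

.AMINO_ACIDS <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE"  # selenomethionine: a polymer residue, treated as protein
)

.NUCLEOTIDES <- c("A", "C", "G", "U", "I", "DA", "DC", "DG", "DT", "DU", "DI")

.STANDARD_RESNAMES <- c(.AMINO_ACIDS, .NUCLEOTIDES)

# Two-letter element symbols that occur as complete PDB atom names of
# non-polymer groups (metals, halides). Matched only for HETATM records:
# polymer names such as "CA" (alpha carbon) or "CD" (delta carbon) are
# single-element carbons.
.TWO_LETTER_ELEMENTS <- c(
  "BR", "CL", "FE", "ZN", "MG", "NA", "MN", "CU", "CO", "NI", "CD",
  "SE", "CA", "K", "LI", "HG", "PT", "AU", "AG", "SR", "CS", "BA",
  "RB", "MO", "AL", "SI", "AS", "IOD"
)

#' Infer a chemical element from a PDB atom name
#'
#' Used when columns 77-78 of an ATOM/HETATM record are blank (common in
#' older depositions). Digits and prime characters are stripped; names
#' beginning with a digit (e.g. "1HB") are hydrogens named with the PDB
#' remoteness convention; a full two-letter element symbol is accepted only
#' for hetero atoms, where "CA" means calcium rather than an alpha carbon.
#'
#' @param name atom name(s), trimmed.
#' @param is_hetero logical, whether each atom comes from a HETATM record.
#' @return character vector of element symbols (never empty; "X" if the
#'   name carries no letter).
#' @keywords internal
infer_element <- function(name, is_hetero = FALSE) {
  is_hetero <- rep_len(is_hetero, length(name))
  vapply(seq_along(name), function(i) {
    nm <- toupper(gsub("['\"*]", "", name[i]))
    if (grepl("^[0-9]", nm)) nm <- sub("^[0-9]+", "", nm)
    letters_only <- gsub("[0-9]", "", nm)
    if (!nzchar(letters_only)) return("X")
    if (is_hetero[i] && letters_only %in% .TWO_LETTER_ELEMENTS) {
      return(substr(letters_only, 1L, 2L))
    }
    substr(letters_only, 1L, 1L)
  }, character(1))
}

.parse_atom_lines <- function(lines) {
  num <- function(s) suppressWarnings(as.numeric(s))
  rec <- substr(lines, 1, 6)
  df <- data.frame(
    serial    = num(substr(lines, 7, 11)),
    name      = trimws(substr(lines, 13, 16)),
    altloc    = trimws(substr(lines, 17, 17)),
    resname   = trimws(substr(lines, 18, 20)),
    chain     = trimws(substr(lines, 22, 22)),
    resseq    = num(substr(lines, 23, 26)),
    icode     = trimws(substr(lines, 27, 27)),
    x         = num(substr(lines, 31, 38)),
    y         = num(substr(lines, 39, 46)),
    z         = num(substr(lines, 47, 54)),
    occupancy = num(substr(lines, 55, 60)),
    bfactor   = num(substr(lines, 61, 66)),
    element   = trimws(substr(lines, 77, 78)),
    is_hetero = trimws(rec) == "HETATM",
    stringsAsFactors = FALSE
  )
  df
}

#' Parse a PDB-format structure
#'
#' Reads ATOM/HETATM records from PDB fixed columns and returns the atom set
#' the B-factor index computation is defined on: only the first MODEL of a
#' multi-model file, and only the first alternate-location configuration of
#' each atom (blank-altloc atoms are always kept; among altloc-labelled
#' duplicates of one atom identity the first in file order wins, regardless
#' of occupancy). Resolution is read from REMARK 2 and R / R-free from
#' REMARK 3 when present. ANISOU records are ignored.
#'
#' @param text PDB content: a character vector of lines, or a single string
#'   containing newlines, or a file path to an existing file.
#' @param pdb_id optional identifier; defaults to the HEADER id code when
#'   present, else "unknown".
#' @return an object of class `pdb_structure`: a list with elements
#'   `pdb_id`, `atoms` (data frame of atom records in file order),
#'   `resolution` (Angstrom, `NA` if absent), `r_work`, `r_free`, `method`,
#'   and `n_nonpositive_b` (count of deposited B-factors <= 0, retained but
#'   flagged).
#' @examples
#' txt <- c(
#'   "ATOM      1  CA  GLY A   1      11.000   0.000   0.000  1.00 20.00           C",
#'   "HETATM    2  C1  LIG A 501       0.000   0.000   0.000  1.00 40.00           C"
#' )
#' m <- parse_pdb(txt)
#' nrow(m$atoms)
#' @export
parse_pdb <- function(text, pdb_id = NULL) {
  if (length(text) == 1L && !grepl("\n", text, fixed = TRUE) &&
      file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  }
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)

  rec <- substr(lines, 1, 6)
  header_id <- NA_character_
  hdr <- lines[rec == "HEADER"]
  if (length(hdr)) {
    cand <- trimws(substr(hdr[1], 63, 66))
    if (nzchar(cand)) header_id <- tolower(cand)
  }

  resolution <- NA_real_
  rem2 <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rem2)) {
    # the remark number itself is not part of the value
    tail_txt <- sub("^REMARK   2 RESOLUTION\\.?", "", rem2[1])
    mt <- regmatches(tail_txt, regexpr("[0-9]+\\.?[0-9]*", tail_txt))
    if (length(mt)) resolution <- as.numeric(mt[1])
  }

  r_work <- NA_real_
  rw <- grep("^REMARK   3   R VALUE\\s+\\(WORKING SET\\)", lines, value = TRUE)
  if (length(rw)) {
    v <- suppressWarnings(as.numeric(trimws(sub(".*:", "", rw[1]))))
    if (is.finite(v)) r_work <- v
  }

  r_free <- NA_real_
  rf <- grep("^REMARK   3   FREE R VALUE\\s*:", lines, value = TRUE)
  if (length(rf)) {
    v <- suppressWarnings(as.numeric(trimws(sub(".*:", "", rf[1]))))
    if (is.finite(v)) r_free <- v
  }

  method <- NA_character_
  exp_l <- lines[rec == "EXPDTA"]
  if (length(exp_l)) method <- trimws(substr(exp_l[1], 11, 79))

  # restrict to the first model when MODEL records exist
  model_idx <- which(rec == "MODEL ")
  if (length(model_idx)) {
    start <- model_idx[1]
    stop_candidates <- c(
      which(rec == "ENDMDL" & seq_along(rec) > start),
      if (length(model_idx) > 1L) model_idx[2],
      length(lines) + 1L
    )
    end <- min(stop_candidates)
    lines <- lines[seq.int(start, min(end, length(lines)))]
    rec <- substr(lines, 1, 6)
  }

  atom_lines <- lines[rec %in% c("ATOM  ", "HETATM")]
  if (!length(atom_lines)) {
    stop("empty structure: no ATOM or HETATM records found", call. = FALSE)
  }

  atoms <- .parse_atom_lines(atom_lines)

  bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z) |
    !is.finite(atoms$bfactor) | !is.finite(atoms$resseq)
  if (any(bad)) {
    warning(sprintf("skipped %d atom record(s) with malformed numeric fields",
                    sum(bad)), call. = FALSE)
    atoms <- atoms[!bad, , drop = FALSE]
    if (!nrow(atoms)) {
      stop("empty structure: all atom records malformed", call. = FALSE)
    }
  }

  blank_el <- !nzchar(atoms$element)
  if (any(blank_el)) {
    atoms$element[blank_el] <-
      infer_element(atoms$name[blank_el], atoms$is_hetero[blank_el])
  }
  atoms$element <- toupper(atoms$element)

  # first-configuration collapsing: one atom per (chain, resseq, icode, name);
  # blank altloc preferred, else the first labelled altloc in file order
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$name, sep = "\r")
  pref <- as.integer(nzchar(atoms$altloc))
  ord <- order(pref, seq_len(nrow(atoms)))
  keep <- sort(ord[!duplicated(key[ord])])
  atoms <- atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL

  if (is.null(pdb_id)) {
    pdb_id <- if (!is.na(header_id)) header_id else "unknown"
  }

  structure(
    list(
      pdb_id = pdb_id,
      atoms = atoms,
      resolution = resolution,
      r_work = r_work,
      r_free = r_free,
      method = method,
      n_nonpositive_b = sum(atoms$bfactor <= 0)
    ),
    class = "pdb_structure"
  )
}

#' Read a PDB file from disk
#'
#' @param path file path.
#' @param pdb_id optional identifier override; defaults to the file's
#'   basename without extension.
#' @return a `pdb_structure` (see [parse_pdb()]).
#' @export
read_pdb <- function(path, pdb_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(pdb_id)) {
    pdb_id <- tolower(tools::file_path_sans_ext(basename(path)))
  }
  parse_pdb(readLines(path, warn = FALSE), pdb_id = pdb_id)
}

#' Fetch a structure from the RCSB PDB by accession code
#'
#' Convenience download wrapper; requires network access.
#'
#' @param pdb_code 4-character PDB accession.
#' @param url_template sprintf template with one `%s` slot for the
#'   upper-cased code.
#' @return a `pdb_structure`.
#' @export
fetch_pdb <- function(pdb_code,
                      url_template = "https://files.rcsb.org/download/%s.pdb") {
  stopifnot(is.character(pdb_code), length(pdb_code) == 1L)
  url <- sprintf(url_template, toupper(pdb_code))
  dest <- tempfile(fileext = ".pdb")
  on.exit(unlink(dest), add = TRUE)
  ok <- tryCatch(
    utils::download.file(url, dest, quiet = TRUE, mode = "wb") == 0L,
    error = function(e) FALSE, warning = function(w) FALSE
  )
  if (!ok || !file.exists(dest) || file.size(dest) == 0) {
    stop("network unavailable or accession not found: ", pdb_code,
         call. = FALSE)
  }
  read_pdb(dest, pdb_id = tolower(pdb_code))
}

.atoms_of <- function(x) {
  if (inherits(x, "pdb_structure")) x$atoms
  else if (inherits(x, "ligand_selection")) x$atoms
  else if (inherits(x, "binding_site")) x$atoms
  else if (is.data.frame(x)) x
  else stop("expected a pdb_structure, selection, or atom data frame",
            call. = FALSE)
}

#' Keep only heavy (non-hydrogen) atoms
#'
#' Removes atoms whose element is H or D, preserving order. The B-factor
#' indices are defined on heavy atoms only.
#'
#' @param x a `pdb_structure`, a ligand/binding-site selection, or an atom
#'   data frame.
#' @return object of the same kind with hydrogen and deuterium atoms removed.
#' @export
heavy_atoms <- function(x) {
  atoms <- .atoms_of(x)
  out <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  rownames(out) <- NULL
  if (is.data.frame(x)) return(out)
  x$atoms <- out
  x
}

.is_water <- function(resname) resname %in% .WATER_RESNAMES

.is_protein_atom <- function(atoms) {
  !atoms$is_hetero | atoms$resname %in% .STANDARD_RESNAMES
}

#' List candidate ligands of a structure
#'
#' Every hetero residue that is neither water nor a standard polymer residue
#' (amino acid, nucleotide, or MSE), one row per residue instance, with its
#' heavy-atom count. An empty result means an apo structure.
#'
#' @param model a `pdb_structure`.
#' @return data frame with columns `chain`, `resname`, `resseq`, `icode`,
#'   `n_heavy`, sorted by chain then residue number.
#' @export
list_ligand_candidates <- function(model) {
  atoms <- heavy_atoms(.atoms_of(model))
  lig <- atoms[atoms$is_hetero &
                 !.is_water(atoms$resname) &
                 !(atoms$resname %in% .STANDARD_RESNAMES), , drop = FALSE]
  if (!nrow(lig)) {
    return(data.frame(chain = character(), resname = character(),
                      resseq = integer(), icode = character(),
                      n_heavy = integer(), stringsAsFactors = FALSE))
  }
  key <- paste(lig$chain, lig$resname, lig$resseq, lig$icode, sep = "\r")
  tab <- lig[!duplicated(key), c("chain", "resname", "resseq", "icode")]
  tab$n_heavy <- as.integer(table(key)[key[!duplicated(key)]])
  tab <- tab[order(tab$chain, tab$resseq, tab$icode), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Select a bound ligand by chain and residue code
#'
#' @param model a `pdb_structure`.
#' @param chain chain identifier.
#' @param resname residue (chemical component) code of the ligand.
#' @param resseq residue number, or `"any"` to take every instance of
#'   `resname` on the chain.
#' @return an object of class `ligand_selection` holding the matched
#'   residue's heavy atoms.
#' @export
select_ligand <- function(model, chain, resname, resseq = "any") {
  if (.is_water(toupper(resname))) {
    stop("water is not a ligand: ", resname, call. = FALSE)
  }
  atoms <- heavy_atoms(.atoms_of(model))
  hit <- atoms$is_hetero & atoms$chain == chain &
    atoms$resname == toupper(resname)
  if (!identical(resseq, "any")) hit <- hit & atoms$resseq == as.integer(resseq)
  sel <- atoms[hit, , drop = FALSE]
  if (!nrow(sel)) {
    cand <- list_ligand_candidates(model)
    avail <- if (nrow(cand)) {
      paste(sprintf("%s:%s:%d", cand$chain, cand$resname, cand$resseq),
            collapse = ", ")
    } else "none (apo structure)"
    stop(sprintf("ligand not found: %s:%s:%s; available candidates: %s",
                 chain, resname, as.character(resseq), avail), call. = FALSE)
  }
  rownames(sel) <- NULL
  structure(
    list(chain = chain, resname = toupper(resname), resseq = resseq,
         atoms = sel),
    class = "ligand_selection"
  )
}

#' Write a structure as PDB-format text
#'
#' Emits standard 80-column ATOM/HETATM records. Round trip through
#' [parse_pdb()] preserves coordinates to 0.001 Angstrom and B-factors to
#' 0.01 Angstrom^2 (the column precision).
#'
#' @param model a `pdb_structure`.
#' @param path optional file path; when given the text is also written there.
#' @return character vector of PDB lines, invisibly when `path` is given.
#' @export
write_pdb <- function(model, path = NULL) {
  atoms <- .atoms_of(model)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z) |
            !is.finite(atoms$bfactor))) {
    stop("non-finite coordinate or B-factor cannot be written", call. = FALSE)
  }
  if (any(atoms$bfactor >= 1000 | atoms$bfactor <= -100)) {
    stop("B-factor overflows columns 61-66 (format %6.2f)", call. = FALSE)
  }
  if (any(abs(atoms$x) >= 10000 | abs(atoms$y) >= 10000 |
            abs(atoms$z) >= 10000)) {
    stop("coordinate overflows an 8.3f column", call. = FALSE)
  }

  fmt_name <- function(name, element) {
    ifelse(nchar(name) >= 4L, substr(name, 1, 4),
           ifelse(nchar(element) == 1L,
                  sprintf(" %-3s", name), sprintf("%-4s", name)))
  }
  occ <- ifelse(is.finite(atoms$occupancy), atoms$occupancy, 1)
  lines <- sprintf(
    "%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(atoms$is_hetero, "HETATM", "ATOM"),
    ifelse(is.finite(atoms$serial), atoms$serial, seq_len(nrow(atoms))),
    fmt_name(atoms$name, atoms$element),
    ifelse(nzchar(atoms$altloc), atoms$altloc, " "),
    atoms$resname,
    ifelse(nzchar(atoms$chain), atoms$chain, " "),
    as.integer(atoms$resseq),
    ifelse(nzchar(atoms$icode), atoms$icode, " "),
    atoms$x, atoms$y, atoms$z, occ, atoms$bfactor,
    atoms$element
  )

  header <- character()
  if (inherits(model, "pdb_structure")) {
    header <- c(header, sprintf("HEADER    %-40s%9s   %4s", "SYNTHETIC OR REWRITTEN ENTRY", "",
                                toupper(substr(model$pdb_id, 1, 4))))
    if (is.finite(model$resolution)) {
      header <- c(header, sprintf(
        "REMARK   2 RESOLUTION. %7.2f ANGSTROMS.", model$resolution))
    }
    if (is.finite(model$r_work)) {
      header <- c(header, sprintf(
        "REMARK   3   R VALUE            (WORKING SET) : %6.3f", model$r_work))
    }
    if (is.finite(model$r_free)) {
      header <- c(header, sprintf(
        "REMARK   3   FREE R VALUE                     : %6.3f", model$r_free))
    }
    if (!is.na(model$method)) {
      header <- c(header, sprintf("EXPDTA    %s", model$method))
    }
  }
  out <- c(header, lines, "END")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat(sprintf("<pdb_structure> %s: %d atoms (%d hetero)\n",
              x$pdb_id, nrow(x$atoms), sum(x$atoms$is_hetero)))
  cat(sprintf("  resolution: %s  R: %s  R-free: %s  method: %s\n",
              format(x$resolution), format(x$r_work), format(x$r_free),
              ifelse(is.na(x$method), "?", x$method)))
  if (x$n_nonpositive_b > 0) {
    cat(sprintf("  warning: %d atom(s) with B-factor <= 0 (retained)\n",
                x$n_nonpositive_b))
  }
  invisible(x)
}

#' @export
print.ligand_selection <- function(x, ...) {
  cat(sprintf("<ligand_selection> %s:%s:%s — %d heavy atoms\n",
              x$chain, x$resname, as.character(x$resseq), nrow(x$atoms)))
  invisible(x)
}
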