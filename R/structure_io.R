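#' Protein structure container
#'
#' An ordered chain of residues, each with an alpha-carbon position and the
#' full set of heavy atoms. Residues are densely renumbered `1..n` in file
#' order; author numbering and insertion codes are discarded at parse time so
#' every downstream index refers to this internal numbering.
#'
#' @param id Structure identifier.
#' @param aa Character vector of one-letter amino-acid codes (`"X"` for
#'   unknown types).
#' @param ca Numeric `n x 3` matrix of alpha-carbon coordinates (Angstrom).
#' @param atoms List of length `n`; element `i` is an `m_i x 3` matrix of the
#'   heavy-atom coordinates of residue `i` (alpha-carbon included), with atom
#'   names as rownames. Hydrogens are never present.
#' @param aa3 Optional character vector of three-letter residue codes (used
#'   when writing PDB output); derived from `aa` when missing.
#' @param label Optional classification label: a list with elements
#'   `family`, `superfamily`, `fold` (character scalars).
#'
#' @return An object of class `"sprot_structure"`.
#' @export
sprot_structure <- function(id, aa, ca, atoms, aa3 = NULL, label = NULL) {
  ca <- as.matrix(ca)
  n <- nrow(ca)
  stopifnot(n >= 1, ncol(ca) == 3, length(aa) == n, length(atoms) == n,
            all(is.finite(ca)))
  if (is.null(aa3)) aa3 <- unname(vapply(aa, aa_three, ""))
  stopifnot(length(aa3) == n)
  if (!is.null(label)) {
    stopifnot(is.list(label), all(c("family", "superfamily", "fold") %in%
                                    names(label)))
  }
  atoms <- lapply(atoms, function(m) {
    m <- as.matrix(m)
    stopifnot(ncol(m) == 3, nrow(m) >= 1, all(is.finite(m)))
    m
  })
  structure(list(id = as.character(id), aa = as.character(aa),
                 ca = unname(ca), atoms = atoms, aa3 = as.character(aa3),
                 label = label),
            class = "sprot_structure")
}

#' @export
print.sprot_structure <- function(x, ...) {
  cat(sprintf("Protein structure '%s': %d residues, %d heavy atoms\n",
              x$id, nrow(x$ca), sum(vapply(x$atoms, nrow, 0L))))
  if (!is.null(x$label))
    cat(sprintf("  label: family=%s superfamily=%s fold=%s\n",
                x$label$family, x$label$superfamily, x$label$fold))
  invisible(x)
}

#' @export
length.sprot_structure <- function(x) nrow(x$ca)

# one-letter -> three-letter code (X -> UNK)
aa_three <- function(a) {
  tab <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
           E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL")
  out <- tab[a]
  ifelse(is.na(out), "UNK", out)
}

# Residue codes acceptable as amino acids when they appear as HETATM records
# (chemically modified residues mapped to their parent type).
.het_aa <- c(MSE = "M", SEC = "C", PYL = "K", SEP = "S", TPO = "T", PTR = "Y",
             CSO = "C", HYP = "P", MLY = "K", M3L = "K", KCX = "K")

#' Read a protein structure from a PDB file
#'
#' Reads ATOM records (plus HETATM records of modified amino acids such as
#' MSE, mapped to their parent residue type) of the first model of a PDB
#' file. Hydrogens are discarded; for atoms with alternate locations the
#' highest-occupancy conformer is kept (ties resolved in file order).
#' Residues lacking an alpha-carbon are dropped with a warning. Surviving
#' residues are renumbered densely from 1 in file order.
#'
#' @param path Path to a PDB file.
#' @param chain Optional chain identifier. Default: the first chain
#'   encountered in the file.
#' @param id Structure id; defaults to the file name without extension.
#' @param label Optional classification label, passed through to the
#'   structure (see [sprot_structure()]).
#'
#' @return A [sprot_structure()].
#' @export
read_pdb_structure <- function(path, chain = NULL, id = NULL, label = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  keep_het <- at$type == "HETATM" & at$resid %in% names(.het_aa)
  at <- at[at$type == "ATOM" | keep_het, , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  at$chain[is.na(at$chain)] <- " "
  if (is.null(chain)) {
    chain <- at$chain[1]
  } else if (!chain %in% at$chain) {
    stop("chain '", chain, "' not found in ", path)
  }
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) stop("no residues for chain '", chain, "' in ", path)

  # drop hydrogens: trust the element symbol when present, else the name
  elesy <- at$elesy
  name_h <- grepl("^H", sub("^[0-9]+", "", at$elety))
  is_h <- ifelse(!is.na(elesy) & elesy != "", elesy == "H", name_h)
  at <- at[!is_h, , drop = FALSE]
  if (nrow(at) == 0) stop("no heavy atoms for chain '", chain, "' in ", path)

  # altlocs: keep the highest-occupancy conformer per (residue, atom name)
  at$insert[is.na(at$insert)] <- ""
  rkey <- paste(at$resno, at$insert, sep = "|")
  akey <- paste(rkey, at$elety, sep = "|")
  if (anyDuplicated(akey)) {
    occ <- at$o
    occ[is.na(occ)] <- 1
    ord <- order(-occ, seq_len(nrow(at)))  # occupancy desc, then file order
    at <- at[ord, , drop = FALSE][!duplicated(akey[ord]), , drop = FALSE]
    at <- at[order(match(paste(at$resno, at$insert, at$elety, sep = "|"),
                         unique(akey))), , drop = FALSE]
    rkey <- paste(at$resno, at$insert, sep = "|")
  }

  res_keys <- unique(rkey)
  aa <- character(0); aa3 <- character(0)
  ca <- NULL; atoms <- list()
  dropped <- character(0)
  for (k in res_keys) {
    sub <- at[rkey == k, , drop = FALSE]
    ica <- which(sub$elety == "CA")
    if (length(ica) == 0) {
      dropped <- c(dropped, paste0(sub$resid[1], k))
      next
    }
    m <- as.matrix(sub[, c("x", "y", "z")])
    rownames(m) <- sub$elety
    resid3 <- sub$resid[1]
    one <- if (resid3 %in% names(.het_aa)) {
      unname(.het_aa[resid3])
    } else {
      suppressWarnings(bio3d::aa321(resid3))
    }
    if (is.na(one) || !one %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
      one <- "X"
    aa <- c(aa, one)
    aa3 <- c(aa3, if (one == "X") "UNK" else resid3)
    ca <- rbind(ca, m[ica[1], ])
    atoms[[length(atoms) + 1L]] <- m
  }
  if (length(dropped) > 0)
    warning("dropped ", length(dropped), " residue(s) without alpha-carbon: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  if (length(aa) == 0) stop("no parseable residues in ", path)
  sprot_structure(id = id, aa = aa, ca = ca, atoms = atoms, aa3 = aa3,
                  label = label)
}

#' Write a structure as a PDB file
#'
#' Writes all heavy atoms with dense residue numbering. An optional rigid
#' transform (a superposition) is applied to the coordinates first.
#'
#' @param structure A [sprot_structure()].
#' @param path Output file path.
#' @param superposition Optional superposition (see [kabsch_superposition()])
#'   applied to all coordinates before writing.
#' @return The path, invisibly.
#' @export
write_structure_pdb <- function(structure, path, superposition = NULL) {
  stopifnot(inherits(structure, "sprot_structure"))
  n <- length(structure)
  xyz <- do.call(rbind, structure$atoms)
  if (!is.null(superposition)) xyz <- apply_superposition(superposition, xyz)
  counts <- vapply(structure$atoms, nrow, 0L)
  resno <- rep(seq_len(n), counts)
  resid <- rep(structure$aa3, counts)
  elety <- unlist(lapply(structure$atoms, rownames), use.names = FALSE)
  if (is.null(elety)) elety <- rep("CA", nrow(xyz))
  bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)), resno = resno,
                   resid = resid, elety = elety,
                   chain = rep("A", nrow(xyz)),
                   eleno = seq_len(nrow(xyz)))
  invisible(path)
}

#' Write a structure alignment to disk
#'
#' Produces three files under a common prefix: `<prefix>.pairs.tsv` with the
#' aligned residue index pairs and their post-superposition distances,
#' `<prefix>.query.pdb` with the query structure transformed into the target
#' frame, and `<prefix>.json` with the summary statistics (TM-score, cover,
#' aligned RMSD).
#'
#' @param alignment A structure alignment (see [tm_score_superposition()]).
#' @param query,target The aligned [sprot_structure()] objects.
#' @param prefix Output path prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_alignment <- function(alignment, query, target, prefix) {
  stopifnot(inherits(alignment, "sprot_alignment"))
  pairs <- alignment$pairs
  if (nrow(pairs) == 0) stop("empty alignment")
  if (any(pairs[, 1] < 1 | pairs[, 1] > length(query)) ||
      any(pairs[, 2] < 1 | pairs[, 2] > length(target)))
    stop("alignment indices out of range for the given structures")
  tsv <- paste0(prefix, ".pairs.tsv")
  pdbf <- paste0(prefix, ".query.pdb")
  jsonf <- paste0(prefix, ".json")
  df <- data.frame(query_index = pairs[, 1], target_index = pairs[, 2],
                   query_aa = query$aa[pairs[, 1]],
                   target_aa = target$aa[pairs[, 2]],
                   distance = round(alignment$distances, 4))
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  write_structure_pdb(query, pdbf, superposition = alignment$superposition)
  jsonlite::write_json(
    list(query = query$id, target = target$id,
         tm_score = alignment$tm_score, cover = alignment$cover,
         rmsd_aligned = alignment$rmsd_aligned,
         n_aligned = nrow(pairs), query_length = alignment$L_T),
    jsonf, auto_unbox = TRUE, digits = NA)
  invisible(c(pairs = tsv, pdb = pdbf, json = jsonf))
}
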