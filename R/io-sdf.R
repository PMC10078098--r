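#' Read an SDF (MOL V2000 multi-record) file
#'
#' One molecule per record; 3D coordinates are retained verbatim. Records
#' that fail to parse are logged with their index and skipped; the batch
#' never aborts. Explicit hydrogens in the connection table are folded into
#' the attached-H counts of their heavy neighbours and removed, so the
#' returned molecules are heavy-atom-only like every other input route.
#'
#' @param path file path
#' @return list of `cvs_molecule` in record order
#' @export
parse_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) return(list())
  # split on $$$$ delimiters
  ends <- grep("^\\$\\$\\$\\$", lines)
  starts <- c(1L, head(ends, -1) + 1L)
  if (length(ends) == 0) { starts <- 1L; ends <- length(lines) }
  out <- list()
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    block <- block[!grepl("^\\$\\$\\$\\$", block)]
    if (all(!nzchar(trimws(block)))) next
    mol <- tryCatch(parse_molblock(block, record_index = r),
      error = function(e) {
        cvs_log(sprintf("skipping SDF record %d: %s", r, conditionMessage(e)))
        NULL
      })
    if (!is.null(mol)) out[[length(out) + 1]] <- mol
  }
  out
}

parse_molblock <- function(block, record_index = NA) {
  if (length(block) < 4) stopf("truncated molblock")
  id <- trimws(block[1])
  if (!nzchar(id)) id <- sprintf("sdf_record_%s", record_index)
  counts <- block[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds)) stopf("bad counts line")
  if (length(block) < 4 + natoms + nbonds) stopf("truncated atom/bond block")
  atom_lines <- block[5:(4 + natoms)]
  el <- character(natoms); xyz <- matrix(0, natoms, 3); chg <- integer(natoms)
  for (i in seq_len(natoms)) {
    ln <- atom_lines[i]
    xyz[i, 1] <- suppressWarnings(as.numeric(substr(ln, 1, 10)))
    xyz[i, 2] <- suppressWarnings(as.numeric(substr(ln, 11, 20)))
    xyz[i, 3] <- suppressWarnings(as.numeric(substr(ln, 21, 30)))
    el[i] <- trimws(substr(ln, 32, 34))
  }
  if (any(is.na(xyz)) || any(!nzchar(el))) stopf("bad atom line")
  ba <- integer(nbonds); bb <- integer(nbonds); bo <- numeric(nbonds)
  if (nbonds > 0) {
    bond_lines <- block[(5 + natoms):(4 + natoms + nbonds)]
    for (k in seq_len(nbonds)) {
      ln <- bond_lines[k]
      ba[k] <- suppressWarnings(as.integer(substr(ln, 1, 3)))
      bb[k] <- suppressWarnings(as.integer(substr(ln, 4, 6)))
      o <- suppressWarnings(as.integer(substr(ln, 7, 9)))
      bo[k] <- if (!is.na(o) && o == 4) 1.5 else as.numeric(o)
    }
    if (any(is.na(ba) | is.na(bb) | is.na(bo))) stopf("bad bond line")
  }
  # M CHG lines override formal charges
  for (ln in grep("^M  CHG", block, value = TRUE)) {
    flds <- scan(text = substring(ln, 7), quiet = TRUE)
    npairs <- flds[1]
    for (p in seq_len(npairs)) {
      chg[flds[2 * p]] <- as.integer(flds[2 * p + 1])
    }
  }
  # fold explicit hydrogens into heavy neighbours
  is_h <- el == "H"
  h_extra <- integer(natoms)
  if (any(is_h) && nbonds > 0) {
    for (k in seq_len(nbonds)) {
      if (is_h[ba[k]] && !is_h[bb[k]]) h_extra[bb[k]] <- h_extra[bb[k]] + 1L
      if (is_h[bb[k]] && !is_h[ba[k]]) h_extra[ba[k]] <- h_extra[ba[k]] + 1L
    }
  }
  keep <- which(!is_h)
  if (length(keep) == 0) stopf("molblock contains no heavy atoms")
  remap <- match(seq_len(natoms), keep)
  kb <- !is_h[ba] & !is_h[bb]
  atoms <- data.frame(element = el[keep], charge = chg[keep],
                      aromatic = FALSE, h = 0L, stringsAsFactors = FALSE)
  bonds <- data.frame(a = remap[ba[kb]], b = remap[bb[kb]], order = bo[kb])
  mol <- new_molecule(id, atoms, bonds, coords = xyz[keep, , drop = FALSE],
                      source = "sdf")
  # implicit H from valence, plus explicit H folded in
  mol <- rehydrogenate(mol)
  extra <- h_extra[keep]
  # where explicit H were present, they replace the valence-derived guess
  has_explicit <- extra > 0
  mol$atoms$h[has_explicit] <- extra[has_explicit]
  mol <- finalize_molecule(mol)
  mol <- perceive_aromaticity(mol)
  mol$source <- "sdf"
  mol
}

#' Write molecules to an SDF file
#'
#' Emits V2000 molblocks (Kekule bond orders are preserved as stored; the
#' aromatic order 1.5 is written as type 4). Molecules without coordinates
#' are written with zeros.
#'
#' @param mols list of `cvs_molecule`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_sdf <- function(mols, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) {
    xyz <- mol$coords
    n <- nrow(mol$atoms)
    if (is.null(xyz)) xyz <- matrix(0, n, 3)
    writeLines(c(mol$id, "  consensusVS", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       n, nrow(mol$bonds)), con)
    for (i in seq_len(n)) {
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         xyz[i, 1], xyz[i, 2], xyz[i, 3], mol$atoms$element[i]), con)
    }
    if (nrow(mol$bonds) > 0) {
      for (k in seq_len(nrow(mol$bonds))) {
        o <- mol$bonds$order[k]
        otype <- if (o == 1.5) 4L else as.integer(o)
        writeLines(sprintf("%3d%3d%3d  0", mol$bonds$a[k], mol$bonds$b[k], otype), con)
      }
    }
    chg <- which(mol$atoms$charge != 0)
    if (length(chg) > 0) {
      writeLines(paste0("M  CHG", sprintf("%3d", length(chg)),
                        paste0(sprintf("%4d%4d", chg, mol$atoms$charge[chg]),
                               collapse = "")), con)
    }
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}
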