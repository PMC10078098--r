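#' Protein-ligand complex structures from PDB
#'
#' Reads ATOM/HETATM records; multi-frame ensembles use MODEL/ENDMDL blocks.
#' Protein atoms are the ATOM records; the ligand is taken from HETATM
#' records (optionally restricted to one residue name). Hydrogens are
#' dropped on read — every geometric operation downstream (contacts, ECIF
#' pairs) is heavy-atom defined.
#'
#' @param path PDB file path
#' @param ligand_resname restrict ligand atoms to this residue name
#'   (default: all HETATM except water)
#' @return list of `cvs_complex` objects, one per frame; each has
#'   `protein` (data.frame: element, x, y, z, chain, res_name, res_num,
#'   atom_name), `ligand` (data.frame: element, x, y, z, atom_name), and
#'   `frame_index` (0-based)
#' @export
read_pdb_frames <- function(path, ligand_resname = NULL) {
  lines <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0) {
    frames <- list(lines)
  } else {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts)) {
      stopf("read_pdb_frames: unbalanced MODEL/ENDMDL in '%s'", path)
    }
    frames <- Map(function(s, e) lines[s:e], model_starts, model_ends)
  }
  out <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    out[[f]] <- parse_pdb_block(frames[[f]], f - 1L, ligand_resname, path)
  }
  out
}

parse_pdb_block <- function(lines, frame_index, ligand_resname, path) {
  rec <- substr(lines, 1, 6)
  keep <- trimws(rec) %in% c("ATOM", "HETATM")
  lines <- lines[keep]
  if (length(lines) == 0) stopf("no ATOM/HETATM records in '%s'", path)
  parse_one <- function(ln) {
    el <- trimws(substr(ln, 77, 78))
    if (!nzchar(el)) {
      # fall back to the atom-name column convention
      el <- gsub("[0-9' ]", "", substr(ln, 13, 14))
      el <- paste0(toupper(substr(el, 1, 1)), tolower(substring(el, 2)))
    }
    el <- paste0(toupper(substr(el, 1, 1)), tolower(substring(el, 2)))
    list(
      record = trimws(substr(ln, 1, 6)),
      atom_name = trimws(substr(ln, 13, 16)),
      res_name = trimws(substr(ln, 18, 20)),
      chain = trimws(substr(ln, 22, 22)),
      res_num = as.integer(substr(ln, 23, 26)),
      x = as.numeric(substr(ln, 31, 38)),
      y = as.numeric(substr(ln, 39, 46)),
      z = as.numeric(substr(ln, 47, 54)),
      element = el
    )
  }
  parsed <- lapply(lines, parse_one)
  df <- do.call(rbind, lapply(parsed, function(p) {
    data.frame(record = p$record, atom_name = p$atom_name, res_name = p$res_name,
               chain = p$chain, res_num = p$res_num,
               x = p$x, y = p$y, z = p$z, element = p$element,
               stringsAsFactors = FALSE)
  }))
  if (any(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z))) {
    stopf("non-finite coordinates in '%s'", path)
  }
  df <- df[df$element != "H", , drop = FALSE]
  prot <- df[df$record == "ATOM", , drop = FALSE]
  lig <- df[df$record == "HETATM" & df$res_name != "HOH", , drop = FALSE]
  if (!is.null(ligand_resname)) lig <- lig[lig$res_name == ligand_resname, , drop = FALSE]
  new_complex(
    protein = prot[, c("element", "x", "y", "z", "chain", "res_name", "res_num", "atom_name")],
    ligand = lig[, c("element", "x", "y", "z", "atom_name")],
    frame_index = frame_index
  )
}

#' Construct a complex structure
#'
#' @param protein data.frame with element, x, y, z, chain, res_name, res_num,
#'   atom_name
#' @param ligand data.frame with element, x, y, z (atom_name optional)
#' @param frame_index 0-based frame number
#' @return a `cvs_complex`
#' @export
new_complex <- function(protein, ligand, frame_index = 0L) {
  protein <- as.data.frame(protein, stringsAsFactors = FALSE)
  ligand <- as.data.frame(ligand, stringsAsFactors = FALSE)
  if (is.null(ligand$atom_name)) ligand$atom_name <- ligand$element
  structure(list(protein = protein, ligand = ligand,
                 frame_index = as.integer(frame_index)),
            class = "cvs_complex")
}

#' @export
print.cvs_complex <- function(x, ...) {
  cat(sprintf("<complex frame %d: %d protein atoms, %d ligand atoms, %d residues>\n",
              x$frame_index, nrow(x$protein), nrow(x$ligand),
              length(unique(paste(x$protein$res_name, x$protein$res_num)))))
  invisible(x)
}

#' Write complex frames to a PDB file
#'
#' Multi-frame input is emitted as MODEL/ENDMDL blocks.
#'
#' @param frames list of `cvs_complex` (or a single one)
#' @param path output path
#' @return invisibly, `path`
#' @export
write_pdb_frames <- function(frames, path) {
  if (inherits(frames, "cvs_complex")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(frames) > 1
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    serial <- 1L
    for (i in seq_len(nrow(fr$protein))) {
      p <- fr$protein[i, ]
      writeLines(sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                         serial, p$atom_name, p$res_name, p$chain, p$res_num,
                         p$x, p$y, p$z, toupper(p$element)), con)
      serial <- serial + 1L
    }
    for (i in seq_len(nrow(fr$ligand))) {
      l <- fr$ligand[i, ]
      writeLines(sprintf("HETATM%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                         serial, l$atom_name, "LIG", "L", 900L,
                         l$x, l$y, l$z, toupper(l$element)), con)
      serial <- serial + 1L
    }
    if (multi) writeLines("ENDMDL", con) else writeLines("END", con)
  }
  invisible(path)
}
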