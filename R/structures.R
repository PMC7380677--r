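#' Read a protein structure into a C-alpha coordinate index
#'
#' Reads a PDB or mmCIF coordinate file (via bio3d) and builds a minimal
#' chain -> residue -> C-alpha index suitable for crosslink mapping.
#' Residue and chain identifiers are the author identifiers exactly as
#' deposited (mmCIF: \code{auth_asym_id} / \code{auth_seq_id}); nothing is
#' renumbered, and chain matching downstream is case-sensitive.
#'
#' Policies applied while indexing:
#' \itemize{
#'   \item \strong{Alternate locations}: the C-alpha with the highest
#'     occupancy is kept; ties go to the altloc appearing first in the file.
#'   \item \strong{Models}: one coordinate model is loaded
#'     (\code{model_index}, default the first), so every crosslink gets a
#'     single distance.
#'   \item \strong{Insertion codes}: crosslink lists carry no insertion
#'     code, so only residues with a blank insertion code are addressable.
#'     When a (chain, number) pair collides across insertion codes the
#'     blank-code residue is kept and the others are skipped with a warning;
#'     residues that exist only with a non-blank code are skipped likewise.
#'   \item \strong{Non-standard residues}: HETATM residues that carry a
#'     C-alpha (e.g. selenomethionine, MSE) are indexed; waters and ligands
#'     without one are excluded. Calcium ions (atom name CA, element Ca)
#'     are never mistaken for alpha-carbons.
#'   \item Polymer (ATOM-record) residues whose C-alpha is absent are
#'     retained in the index without a coordinate, so lookups can
#'     distinguish "residue present but C-alpha unresolved" from "residue
#'     absent".
#' }
#'
#' @param path path to a coordinate file.
#' @param format \code{"auto"} (by file extension: .cif/.mmcif is mmCIF,
#'   anything else PDB), \code{"pdb"}, or \code{"mmcif"}.
#' @param model_index which coordinate model to load from a multi-model
#'   file (1-based).
#' @param quiet suppress the summary message.
#' @return an object of class \code{xl_structure}: a list with
#'   \code{source_name} (file stem), \code{model_index}, and
#'   \code{residues}, a data frame with columns \code{chain}, \code{resno},
#'   \code{resid}, \code{has_ca}, \code{x}, \code{y}, \code{z}.
#' @seealso \code{\link{get_ca}}, \code{\link{map_dataset}}
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           model_index = 1L, quiet = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("cannot read structure file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  reader <- if (format == "mmcif") bio3d::read.cif else bio3d::read.pdb
  pdb <- tryCatch(
    suppressWarnings(reader(path, multi = TRUE, rm.alt = FALSE,
                            verbose = FALSE)),
    error = function(e) stop("failed to parse ", path, " as ", format,
                             ": ", conditionMessage(e), call. = FALSE))
  n_models <- nrow(pdb$xyz)
  if (is.null(n_models)) n_models <- 1L
  model_index <- as.integer(model_index)
  if (model_index < 1L || model_index > n_models)
    stop("model_index ", model_index, " out of range; ", path,
         " has models 1..", n_models)
  atoms <- pdb$atom
  if (model_index > 1L) {
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  }
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$elesy[is.na(atoms$elesy)] <- ""
  atoms$o[is.na(atoms$o)] <- 1.0
  atoms$chain[is.na(atoms$chain)] <- ""

  # alpha-carbons: atom name CA but not element Ca (calcium ions)
  is_ca <- atoms$elety == "CA" & toupper(atoms$elesy) != "CA" &
    atoms$resid != "HOH"
  # residues worth indexing: anything with a C-alpha, plus polymer (ATOM)
  # residues whose C-alpha is unresolved
  rkey <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  keep_res <- unique(rkey[is_ca | atoms$type == "ATOM"])
  sel <- rkey %in% keep_res & nzchar(atoms$chain)
  atoms <- atoms[sel, , drop = FALSE]
  is_ca <- is_ca[sel]
  if (nrow(atoms) == 0L || !any(is_ca))
    stop("no mappable residues: ", path,
         " contains no polymer chain with a C-alpha atom")

  # one row per (chain, resno, insert), in file order
  rkey <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  first <- !duplicated(rkey)
  res <- data.frame(chain = atoms$chain[first],
                    resno = as.integer(atoms$resno[first]),
                    icode = atoms$insert[first],
                    resid = atoms$resid[first],
                    stringsAsFactors = FALSE)

  # insertion-code policy: crosslink lists address (chain, resno) only, so
  # residues with a non-blank insertion code are never addressable; drop
  # them (keeping any blank-code residue with the same number) with a
  # warning naming the skipped ones
  drop <- res$icode != ""
  if (any(drop)) {
    warning("skipping ", sum(drop), " residue(s) with insertion codes ",
            "(not addressable by crosslink lists): ",
            paste(utils::head(paste0(res$chain[drop], "/", res$resno[drop],
                                     res$icode[drop]), 10), collapse = ", "),
            if (sum(drop) > 10) ", ..." else "", call. = FALSE)
    res <- res[!drop, , drop = FALSE]
  }

  # altloc policy per residue: highest occupancy, ties to file order
  res$has_ca <- FALSE
  res$x <- res$y <- res$z <- NA_real_
  ca <- atoms[is_ca & atoms$insert == "", , drop = FALSE]
  if (nrow(ca) > 0L) {
    cak <- paste(ca$chain, ca$resno, sep = "\r")
    ord <- order(cak, -ca$o, seq_len(nrow(ca)))
    ca <- ca[ord[!duplicated(cak[ord])], , drop = FALSE]
    idx <- match(paste(ca$chain, ca$resno, sep = "\r"),
                 paste(res$chain, res$resno, sep = "\r"))
    ok <- !is.na(idx)
    res$has_ca[idx[ok]] <- TRUE
    res$x[idx[ok]] <- ca$x[ok]
    res$y[idx[ok]] <- ca$y[ok]
    res$z[idx[ok]] <- ca$z[ok]
  }
  res$icode <- NULL
  rownames(res) <- NULL

  model <- structure(
    list(source_name = tools::file_path_sans_ext(basename(path)),
         model_index = model_index,
         residues = res),
    class = "xl_structure")
  if (!quiet) {
    tab <- table(res$chain)
    message("read ", basename(path), ": ", length(tab), " chain(s), ",
            nrow(res), " residue(s), ", sum(res$has_ca), " C-alpha(s) [",
            paste(names(tab), tab, sep = ":", collapse = " "), "]")
  }
  model
}

#' @export
print.xl_structure <- function(x, ...) {
  cat("C-alpha index '", x$source_name, "' (model ", x$model_index, ")\n",
      sep = "")
  tab <- table(x$residues$chain)
  cat("  chains:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  cat("  residues:", nrow(x$residues),
      " with C-alpha:", sum(x$residues$has_ca), "\n")
  invisible(x)
}

#' Look up a C-alpha coordinate
#'
#' Total lookup: absence is a value, not an error. Use
#' \code{\link{ca_status}} to distinguish why a lookup failed.
#'
#' @param model an \code{\link{read_structure}} result.
#' @param chain_id chain identifier (case-sensitive, exact).
#' @param seq_num author residue number.
#' @return numeric \code{c(x, y, z)} in Angstrom, or \code{NULL} when the
#'   chain or residue is absent or the residue has no C-alpha.
#' @export
get_ca <- function(model, chain_id, seq_num) {
  stopifnot(inherits(model, "xl_structure"))
  r <- model$residues
  i <- which(r$chain == chain_id & r$resno == seq_num)
  if (length(i) == 0L || !r$has_ca[i[1]]) return(NULL)
  c(r$x[i[1]], r$y[i[1]], r$z[i[1]])
}

#' Reason a C-alpha lookup succeeds or fails
#'
#' @inheritParams get_ca
#' @return one of \code{"ok"}, \code{"chain_missing"},
#'   \code{"residue_missing"}, \code{"ca_missing"}.
#' @export
ca_status <- function(model, chain_id, seq_num) {
  stopifnot(inherits(model, "xl_structure"))
  r <- model$residues
  if (!chain_id %in% r$chain) return("chain_missing")
  i <- which(r$chain == chain_id & r$resno == seq_num)
  if (length(i) == 0L) return("residue_missing")
  if (!r$has_ca[i[1]]) return("ca_missing")
  "ok"
}
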