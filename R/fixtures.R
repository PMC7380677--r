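#' Specify a synthetic linear C-alpha trace
#'
#' A trace spec describes one or more protein chains laid out as straight
#' lines of C-alpha atoms, so that every inter-residue distance has a closed
#' form: within a chain, residues \code{i} and \code{j} are
#' \code{|i - j| * spacing} apart; across chains \code{k} and \code{m} the
#' traces are parallel lines \code{|k - m| * chain_offset} apart, giving
#' \code{sqrt(((i - j) * spacing)^2 + ((k - m) * chain_offset)^2)}.
#' This makes mapped distances checkable against arithmetic rather than
#' against the mapping code itself.
#'
#' Spacing values should be exactly representable at 3 decimal places (PDB
#' coordinate precision) so the closed form is exact; the default 3.8 A is
#' the canonical C-alpha virtual bond length.
#'
#' @param chains named integer vector: names are single-character chain IDs,
#'   values are residue counts (residues numbered 1..n).
#' @param spacing inter-residue spacing along each chain, in Angstrom.
#' @param chain_offset perpendicular offset between consecutive chains, in
#'   Angstrom.
#' @param omit data frame with columns \code{chain}, \code{resno}: residues
#'   left out of the file entirely (emulating unresolved residues).
#' @param no_ca data frame with columns \code{chain}, \code{resno}: residues
#'   written with a CB atom only, no C-alpha.
#' @return an object of class \code{trace_spec}.
#' @examples
#' spec <- trace_spec(c(A = 10, B = 5), spacing = 3.8)
#' @export
trace_spec <- function(chains = c(A = 10), spacing = 3.8, chain_offset = 50,
                       omit = NULL, no_ca = NULL) {
  if (is.null(names(chains)) || any(!nzchar(names(chains))))
    stop("'chains' must be a named vector (names are chain IDs)")
  if (any(nchar(names(chains)) != 1L))
    stop("PDB fixture chain IDs must be single characters")
  if (anyDuplicated(names(chains)))
    stop("chain IDs must be unique")
  chain_ids <- names(chains)
  chains <- as.integer(chains)
  names(chains) <- chain_ids
  if (any(chains < 1L)) stop("each chain needs at least one residue")
  if (!is.numeric(spacing) || spacing <= 0) stop("'spacing' must be > 0")
  if (!is.numeric(chain_offset) || chain_offset <= 0)
    stop("'chain_offset' must be > 0")
  omit <- check_residue_table(omit, chains, "omit")
  no_ca <- check_residue_table(no_ca, chains, "no_ca")
  structure(list(chains = chains, spacing = spacing,
                 chain_offset = chain_offset, omit = omit, no_ca = no_ca),
            class = "trace_spec")
}

check_residue_table <- function(x, chains, what) {
  if (is.null(x)) return(data.frame(chain = character(), resno = integer()))
  if (!is.data.frame(x) || !all(c("chain", "resno") %in% names(x)))
    stop("'", what, "' must be a data frame with columns chain, resno")
  x$chain <- as.character(x$chain)
  x$resno <- as.integer(x$resno)
  bad <- !(x$chain %in% names(chains)) | x$resno < 1L |
    x$resno > chains[x$chain]
  bad[is.na(bad)] <- TRUE
  if (any(bad))
    stop("'", what, "' references residues outside the trace: ",
         paste(x$chain[bad], x$resno[bad], sep = "/", collapse = ", "))
  x[, c("chain", "resno")]
}

#' Closed-form C-alpha distance for a trace spec
#'
#' The analytic distance between two residues of a linear trace, evaluated
#' independently of any coordinate file or structure reader. Used as the
#' oracle in tests of the mapping pipeline.
#'
#' @param spec a \code{\link{trace_spec}}.
#' @param chain_1,res_1,chain_2,res_2 endpoint addresses (vectorized).
#' @return numeric vector of distances in Angstrom.
#' @export
trace_distance <- function(spec, chain_1, res_1, chain_2, res_2) {
  k <- match(chain_1, names(spec$chains))
  m <- match(chain_2, names(spec$chains))
  if (anyNA(k) || anyNA(m)) stop("chain not in spec")
  dx <- (res_1 - res_2) * spec$spacing
  dy <- (k - m) * spec$chain_offset
  sqrt(dx^2 + dy^2)
}

#' Generate a linear C-alpha trace as PDB or mmCIF text
#'
#' Writes chain k (k = 1, 2, ...) along the line y = (k-1) * chain_offset,
#' z = 0, with residue i's C-alpha at x = (i-1) * spacing. Residues listed
#' in \code{spec$omit} are absent; residues in \code{spec$no_ca} carry a CB
#' atom only. All residues are ALA with occupancy 1.00 at PDB precision
#' (3 decimals).
#'
#' @param spec a \code{\link{trace_spec}}.
#' @param path optional output file; when NULL the text is returned only.
#' @param format \code{"pdb"} (fixed-column ATOM records) or \code{"mmcif"}
#'   (an atom_site loop with auth_* addressing).
#' @return character vector of file lines, invisibly when \code{path} is set.
#' @export
make_linear_ca_trace <- function(spec, path = NULL,
                                 format = c("pdb", "mmcif")) {
  stopifnot(inherits(spec, "trace_spec"))
  format <- match.arg(format)
  rows <- NULL
  serial <- 0L
  for (k in seq_along(spec$chains)) {
    ch <- names(spec$chains)[k]
    for (i in seq_len(spec$chains[k])) {
      if (any(spec$omit$chain == ch & spec$omit$resno == i)) next
      serial <- serial + 1L
      atom <- if (any(spec$no_ca$chain == ch & spec$no_ca$resno == i))
        "CB" else "CA"
      rows <- rbind(rows, data.frame(
        serial = serial, atom = atom, chain = ch, resno = i,
        x = (i - 1) * spec$spacing, y = (k - 1) * spec$chain_offset, z = 0))
    }
  }
  if (is.null(rows)) stop("trace spec produced no atoms")
  lines <- if (format == "pdb") {
    c(sprintf(
      "ATOM  %5d  %-3s ALA %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      rows$serial, rows$atom, rows$chain, rows$resno,
      rows$x, rows$y, rows$z),
      "END")
  } else {
    c("data_fixture",
      "loop_",
      "_atom_site.group_PDB",
      "_atom_site.id",
      "_atom_site.type_symbol",
      "_atom_site.label_atom_id",
      "_atom_site.label_alt_id",
      "_atom_site.label_comp_id",
      "_atom_site.label_asym_id",
      "_atom_site.label_entity_id",
      "_atom_site.label_seq_id",
      "_atom_site.pdbx_PDB_ins_code",
      "_atom_site.Cartn_x",
      "_atom_site.Cartn_y",
      "_atom_site.Cartn_z",
      "_atom_site.occupancy",
      "_atom_site.B_iso_or_equiv",
      "_atom_site.auth_seq_id",
      "_atom_site.auth_comp_id",
      "_atom_site.auth_asym_id",
      "_atom_site.auth_atom_id",
      "_atom_site.pdbx_PDB_model_num",
      sprintf("ATOM %d C %s . ALA %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 %d ALA %s %s 1",
              rows$serial, rows$atom, rows$chain, rows$resno,
              rows$x, rows$y, rows$z, rows$resno, rows$chain, rows$atom),
      "#")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Generate a crosslink list fixture in the Jwalk dialect
#'
#' Emits one pipe-delimited line per entry, crosslinks as
#' \code{res1|chain1|res2|chain2|} and mono-links as \code{res|chain|},
#' in the order given. Residue numbers may deliberately fall outside the
#' trace to create missing-residue cases downstream.
#'
#' @param links data frame with columns \code{res_1}, \code{chain_1},
#'   \code{res_2}, \code{chain_2}; rows with NA in \code{res_2}/
#'   \code{chain_2} become mono-links.
#' @param spec optional \code{\link{trace_spec}}; when given, chain IDs in
#'   \code{links} must exist in the spec.
#' @param path optional output file.
#' @return character vector of file lines, invisibly when \code{path} is set.
#' @export
make_xl_fixture <- function(links, spec = NULL, path = NULL) {
  stopifnot(is.data.frame(links),
            all(c("res_1", "chain_1") %in% names(links)))
  if (!"res_2" %in% names(links)) links$res_2 <- NA_integer_
  if (!"chain_2" %in% names(links)) links$chain_2 <- NA_character_
  if (!is.null(spec)) {
    used <- c(links$chain_1, links$chain_2)
    used <- used[!is.na(used)]
    if (!all(used %in% names(spec$chains)))
      stop("link chain IDs not defined in the trace spec: ",
           paste(setdiff(used, names(spec$chains)), collapse = ", "))
  }
  mono <- is.na(links$res_2)
  lines <- ifelse(mono,
    sprintf("%d|%s|", links$res_1, links$chain_1),
    sprintf("%d|%s|%d|%s|", links$res_1, links$chain_1,
            links$res_2, links$chain_2))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
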