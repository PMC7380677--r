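#' Parse a crosslink / mono-link list (Jwalk dialect)
#'
#' Reads the pipe-delimited format used by Jwalk and related XL-MS tools:
#' one entry per line, a crosslink as \code{res1|chain1|res2|chain2|} and a
#' dead-end mono-link as \code{res|chain|}. The trailing pipe is optional,
#' surrounding whitespace per field is stripped, blank lines and lines
#' starting with \code{#} are ignored.
#'
#' Exact duplicate crosslinks (after canonical endpoint ordering, so
#' \code{10|A|20|A|} and \code{20|A|10|A|} are the same link) are removed
#' with a warning; the first occurrence's original orientation is kept for
#' labels. Self-links (identical endpoints) are invalid zero-length
#' restraints and are excluded with a warning. Score columns or any other
#' extra fields are a format error: filtering by identification score
#' belongs upstream in the XL-MS search software.
#'
#' @param path path to the list file.
#' @return an object of class \code{xl_dataset}: a list with
#'   \code{crosslinks} (data frame: \code{chain_1}, \code{res_1},
#'   \code{chain_2}, \code{res_2}, \code{source_line}), \code{monolinks}
#'   (data frame: \code{chain}, \code{res}, \code{source_line}),
#'   \code{source_path}, and bookkeeping counts \code{n_lines},
#'   \code{n_skipped}, \code{n_duplicates}, \code{n_selflinks}.
#' @export
parse_xl_file <- function(path) {
  if (!file.exists(path)) stop("cannot read crosslink file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  trimmed <- trimws(lines)
  skip <- !nzchar(trimmed) | startsWith(trimmed, "#")
  if (length(lines) == 0L || all(skip))
    warning("empty crosslink file: ", path, call. = FALSE)

  xl <- list(); ml <- list()
  for (i in which(!skip)) {
    body <- sub("\\|$", "", trimmed[i])
    fields <- trimws(strsplit(body, "|", fixed = TRUE)[[1]])
    if (!length(fields) %in% c(2L, 4L))
      stop("line ", i, " of ", path, ": expected 2 (mono-link) or 4 ",
           "(crosslink) fields, got ", length(fields), ": \"",
           lines[i], "\"")
    resf <- fields[seq(1L, length(fields), by = 2L)]
    resn <- suppressWarnings(as.integer(resf))
    if (anyNA(resn) || any(resn != as.numeric(resf)))
      stop("line ", i, " of ", path, ": residue number is not an integer: \"",
           lines[i], "\"")
    if (any(!nzchar(fields[seq(2L, length(fields), by = 2L)])))
      stop("line ", i, " of ", path, ": empty chain identifier: \"",
           lines[i], "\"")
    if (length(fields) == 4L) {
      xl[[length(xl) + 1L]] <- data.frame(
        chain_1 = fields[2], res_1 = resn[1],
        chain_2 = fields[4], res_2 = resn[2],
        source_line = i, stringsAsFactors = FALSE)
    } else {
      ml[[length(ml) + 1L]] <- data.frame(
        chain = fields[2], res = resn[1], source_line = i,
        stringsAsFactors = FALSE)
    }
  }
  crosslinks <- if (length(xl)) do.call(rbind, xl) else
    data.frame(chain_1 = character(), res_1 = integer(),
               chain_2 = character(), res_2 = integer(),
               source_line = integer(), stringsAsFactors = FALSE)
  monolinks <- if (length(ml)) do.call(rbind, ml) else
    data.frame(chain = character(), res = integer(),
               source_line = integer(), stringsAsFactors = FALSE)

  # self-links carry no distance information
  self <- crosslinks$chain_1 == crosslinks$chain_2 &
    crosslinks$res_1 == crosslinks$res_2
  if (any(self)) {
    warning("excluding ", sum(self), " self-link(s) (identical endpoints) ",
            "at line(s) ", paste(crosslinks$source_line[self],
                                 collapse = ", "), call. = FALSE)
    crosslinks <- crosslinks[!self, , drop = FALSE]
  }

  # deduplicate on canonical endpoint order, keep first original orientation
  key <- canonical_link_key(crosslinks)
  dup <- duplicated(key)
  if (any(dup)) {
    warning("removing ", sum(dup), " duplicate crosslink(s) at line(s) ",
            paste(crosslinks$source_line[dup], collapse = ", "),
            call. = FALSE)
    crosslinks <- crosslinks[!dup, , drop = FALSE]
  }
  dupml <- duplicated(paste(monolinks$chain, monolinks$res, sep = "\r"))
  if (any(dupml)) {
    warning("removing ", sum(dupml), " duplicate mono-link(s) at line(s) ",
            paste(monolinks$source_line[dupml], collapse = ", "),
            call. = FALSE)
    monolinks <- monolinks[!dupml, , drop = FALSE]
  }
  rownames(crosslinks) <- rownames(monolinks) <- NULL

  structure(list(crosslinks = crosslinks, monolinks = monolinks,
                 source_path = path,
                 n_lines = length(lines), n_skipped = sum(skip),
                 n_duplicates = sum(dup) + sum(dupml),
                 n_selflinks = sum(self)),
            class = "xl_dataset")
}

# canonical key: smaller (chain, resno) lexicographic pair first
canonical_link_key <- function(xl) {
  if (nrow(xl) == 0L) return(character())
  a_first <- xl$chain_1 < xl$chain_2 |
    (xl$chain_1 == xl$chain_2 & xl$res_1 <= xl$res_2)
  ifelse(a_first,
         paste(xl$chain_1, xl$res_1, xl$chain_2, xl$res_2, sep = "\r"),
         paste(xl$chain_2, xl$res_2, xl$chain_1, xl$res_1, sep = "\r"))
}

#' @export
print.xl_dataset <- function(x, ...) {
  cat("XL-MS dataset: ", nrow(x$crosslinks), " crosslink(s), ",
      nrow(x$monolinks), " mono-link(s)", sep = "")
  if (x$n_duplicates + x$n_selflinks > 0)
    cat(" (", x$n_duplicates, " duplicate(s) and ", x$n_selflinks,
        " self-link(s) dropped)", sep = "")
  cat("\n  source:", x$source_path, "\n")
  invisible(x)
}

#' Write a crosslink dataset in the Jwalk dialect
#'
#' Emits one line per crosslink (\code{res1|chain1|res2|chain2|}) then per
#' mono-link (\code{res|chain|}), trailing pipe included. Re-parsing the
#' written file reproduces the dataset.
#'
#' @param dataset an \code{xl_dataset}.
#' @param path output file path.
#' @export
write_xl_file <- function(dataset, path) {
  stopifnot(inherits(dataset, "xl_dataset"))
  xl <- dataset$crosslinks
  ml <- dataset$monolinks
  lines <- c(
    sprintf("%d|%s|%d|%s|", xl$res_1, xl$chain_1, xl$res_2, xl$chain_2),
    sprintf("%d|%s|", ml$res, ml$chain))
  writeLines(lines, path)
  invisible(path)
}

#' Export a mapping report as CSV
#'
#' One row per crosslink and per mono-link: \code{chain_1}, \code{res_1},
#' \code{chain_2}, \code{res_2} (blank for mono-links),
#' \code{distance_angstrom} (1 decimal place; blank when the link cannot be
#' mapped), \code{status} (\code{satisfied}, \code{violated}, or
#' \code{missing}; for a mono-link, satisfied means its residue's C-alpha
#' is present), and \code{topology} (\code{intra}, \code{inter}, or
#' \code{monolink}).
#'
#' @param report a \code{\link{map_dataset}} result.
#' @param path output file path.
#' @export
export_csv <- function(report, path) {
  stopifnot(inherits(report, "xl_report"))
  xl <- report$crosslinks
  ml <- report$monolinks
  rows <- data.frame(
    chain_1 = c(xl$chain_1, ml$chain),
    res_1 = c(xl$res_1, ml$res),
    chain_2 = c(xl$chain_2, rep("", nrow(ml))),
    res_2 = c(as.character(xl$res_2), rep("", nrow(ml))),
    distance_angstrom = c(
      ifelse(is.na(xl$distance), "",
             formatC(xl$distance, format = "f", digits = 1)),
      rep("", nrow(ml))),
    status = c(xl$status, ifelse(ml$present, "satisfied", "missing")),
    topology = c(xl$topology, rep("monolink", nrow(ml))),
    stringsAsFactors = FALSE)
  utils::write.table(rows, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
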