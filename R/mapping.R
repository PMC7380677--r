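#' Euclidean distance between two coordinates
#'
#' @param p,q numeric length-3 coordinates (Angstrom).
#' @return the distance in Angstrom.
#' @export
euclidean_distance <- function(p, q) {
  stopifnot(length(p) == 3L, length(q) == 3L,
            all(is.finite(p)), all(is.finite(q)))
  sqrt(sum((p - q)^2))
}

#' Classify a distance against the spacer-arm threshold
#'
#' A crosslink is \emph{violated} when its C-alpha - C-alpha distance is
#' strictly greater than the threshold, and \emph{satisfied} otherwise; a
#' link exactly at the threshold is satisfied. Classification always uses
#' the full-precision distance, never the rounded display value.
#'
#' @param distance numeric vector of distances (Angstrom), each >= 0.
#' @param threshold spacer-arm distance threshold in Angstrom (> 0). The
#'   default 27 suits DSBU, which bridges residues up to roughly 27-30 A
#'   C-alpha - C-alpha.
#' @return character vector, \code{"satisfied"} or \code{"violated"}.
#' @export
classify_distance <- function(distance, threshold = 27) {
  stopifnot(is.numeric(distance), all(distance >= 0, na.rm = TRUE),
            is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  ifelse(distance > threshold, "violated", "satisfied")
}

#' Map one crosslink onto a structure
#'
#' @param model an \code{\link{read_structure}} result.
#' @param chain_1,res_1,chain_2,res_2 the two endpoints.
#' @param threshold spacer-arm threshold in Angstrom.
#' @return one-row data frame with columns \code{chain_1}, \code{res_1},
#'   \code{chain_2}, \code{res_2}, \code{distance}, \code{status},
#'   \code{topology}, \code{absent_endpoints}. Missing residues are a
#'   status, not an error; a warning names each unresolvable endpoint.
#' @export
map_crosslink <- function(model, chain_1, res_1, chain_2, res_2,
                          threshold = 27) {
  out <- map_crosslink_table(
    model,
    data.frame(chain_1 = chain_1, res_1 = res_1,
               chain_2 = chain_2, res_2 = res_2,
               stringsAsFactors = FALSE),
    threshold)
  if (out$status == "missing")
    warning("crosslink ", res_1, "|", chain_1, "-", res_2, "|", chain_2,
            " cannot be mapped: residue(s) ", out$absent_endpoints,
            " not in structure '", model$source_name, "'", call. = FALSE)
  out
}

# vectorized core shared by map_crosslink and map_dataset
map_crosslink_table <- function(model, xl, threshold) {
  r <- model$residues
  key <- paste(r$chain, r$resno, sep = "\r")
  i1 <- match(paste(xl$chain_1, xl$res_1, sep = "\r"), key)
  i2 <- match(paste(xl$chain_2, xl$res_2, sep = "\r"), key)
  ok1 <- !is.na(i1) & r$has_ca[pmax(i1, 1L)]
  ok2 <- !is.na(i2) & r$has_ca[pmax(i2, 1L)]
  d <- rep(NA_real_, nrow(xl))
  both <- ok1 & ok2
  if (any(both)) {
    d[both] <- sqrt((r$x[i1[both]] - r$x[i2[both]])^2 +
                    (r$y[i1[both]] - r$y[i2[both]])^2 +
                    (r$z[i1[both]] - r$z[i2[both]])^2)
  }
  absent <- character(nrow(xl))
  absent[!ok1] <- paste0(xl$chain_1[!ok1], "/", xl$res_1[!ok1])
  absent[!ok2] <- trimws(paste(
    absent[!ok2],
    paste0(xl$chain_2[!ok2], "/", xl$res_2[!ok2]), sep = " "))
  data.frame(
    chain_1 = xl$chain_1, res_1 = xl$res_1,
    chain_2 = xl$chain_2, res_2 = xl$res_2,
    distance = d,
    status = ifelse(both, classify_distance(ifelse(both, d, 0), threshold),
                    "missing"),
    topology = ifelse(xl$chain_1 == xl$chain_2, "intra", "inter"),
    absent_endpoints = absent,
    stringsAsFactors = FALSE)
}

#' Map a crosslink dataset onto a structure
#'
#' Joins every crosslink and mono-link in the dataset to the structure's
#' C-alpha index, in file order: computes each C-alpha - C-alpha Euclidean
#' distance, classifies it as satisfied or violated against the spacer-arm
#' threshold, types it as intra- or inter-chain from the chain identifiers,
#' and flags links whose residues are absent from (or unresolved in) the
#' structure as missing. Mono-links get a present/missing flag only; no
#' distance is defined for a single site, so they never enter the
#' satisfied/violated tallies.
#'
#' @param model an \code{\link{read_structure}} result.
#' @param dataset an \code{\link{parse_xl_file}} result.
#' @param threshold spacer-arm threshold in Angstrom (default 27, suitable
#'   for DSBU).
#' @param include_monolinks map mono-links as well (default TRUE).
#' @param object_prefix prefix for per-link graphics object names.
#' @param warn_missing emit a consolidated warning naming unmappable links.
#' @return an object of class \code{xl_report}: a list with \code{config},
#'   \code{crosslinks}, \code{monolinks}, \code{counts}
#'   (see \code{\link{summary_counts}}), and \code{structure_name}.
#' @examples
#' spec <- trace_spec(c(A = 10), spacing = 10)
#' pdb <- tempfile(fileext = ".pdb")
#' make_linear_ca_trace(spec, pdb)
#' xlf <- tempfile(fileext = ".txt")
#' make_xl_fixture(data.frame(res_1 = 1, chain_1 = "A",
#'                            res_2 = 3, chain_2 = "A"), spec, xlf)
#' model <- read_structure(pdb, quiet = TRUE)
#' report <- map_dataset(model, parse_xl_file(xlf))
#' report$crosslinks$distance  # 20
#' @export
map_dataset <- function(model, dataset, threshold = 27,
                        include_monolinks = TRUE, object_prefix = "xl",
                        warn_missing = TRUE) {
  stopifnot(inherits(model, "xl_structure"), inherits(dataset, "xl_dataset"),
            is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  xl <- map_crosslink_table(model, dataset$crosslinks, threshold)
  xl$object_name <- object_name(xl$res_1, xl$chain_1, xl$res_2, xl$chain_2,
                                prefix = object_prefix)
  ml <- dataset$monolinks
  if (!include_monolinks) ml <- ml[0, , drop = FALSE]
  r <- model$residues
  key <- paste(r$chain, r$resno, sep = "\r")
  mi <- match(paste(ml$chain, ml$res, sep = "\r"), key)
  ml_out <- data.frame(
    chain = ml$chain, res = ml$res,
    present = !is.na(mi) & r$has_ca[pmax(mi, 1L)],
    stringsAsFactors = FALSE)
  ml_out$object_name <- object_name(ml_out$res, ml_out$chain,
                                    prefix = object_prefix)
  if (warn_missing && any(xl$status == "missing")) {
    miss <- xl$absent_endpoints[xl$status == "missing"]
    warning(sum(xl$status == "missing"), " crosslink(s) reference residues ",
            "not in structure '", model$source_name, "': ",
            paste(utils::head(unique(unlist(strsplit(miss, " "))), 15),
                  collapse = ", "),
            if (length(unique(unlist(strsplit(miss, " ")))) > 15)
              ", ..." else "",
            call. = FALSE)
  }
  new_xl_report(
    config = list(threshold_angstrom = threshold,
                  include_monolinks = include_monolinks),
    crosslinks = xl, monolinks = ml_out,
    structure_name = model$source_name)
}

new_xl_report <- function(config, crosslinks, monolinks, structure_name) {
  counts <- summary_counts(crosslinks, monolinks)
  structure(list(config = config, crosslinks = crosslinks,
                 monolinks = monolinks, counts = counts,
                 structure_name = structure_name),
            class = "xl_report")
}

#' Conservation-checked summary tallies for a mapping report
#'
#' Recomputes the tallies from the per-link tables and asserts the
#' conservation identities: satisfied + violated = displayable,
#' displayable + missing = total, intra + inter = total.
#'
#' @param crosslinks,monolinks per-link tables from an \code{xl_report} (an
#'   \code{xl_report} itself may be given as the first argument).
#' @return a list of non-negative integers: \code{n_total},
#'   \code{n_displayable}, \code{n_satisfied}, \code{n_violated},
#'   \code{n_missing}, \code{n_intra}, \code{n_inter}, \code{n_monolinks},
#'   \code{n_monolinks_missing}.
#' @export
summary_counts <- function(crosslinks, monolinks = NULL) {
  if (inherits(crosslinks, "xl_report")) {
    monolinks <- crosslinks$monolinks
    crosslinks <- crosslinks$crosslinks
  }
  s <- crosslinks$status
  counts <- list(
    n_total = nrow(crosslinks),
    n_displayable = sum(s != "missing"),
    n_satisfied = sum(s == "satisfied"),
    n_violated = sum(s == "violated"),
    n_missing = sum(s == "missing"),
    n_intra = sum(crosslinks$topology == "intra"),
    n_inter = sum(crosslinks$topology == "inter"),
    n_monolinks = nrow(monolinks),
    n_monolinks_missing = sum(!monolinks$present))
  stopifnot(counts$n_satisfied + counts$n_violated == counts$n_displayable,
            counts$n_displayable + counts$n_missing == counts$n_total,
            counts$n_intra + counts$n_inter == counts$n_total)
  counts
}

#' Show or hide crosslink classes in a report
#'
#' Mirrors the display toggles of interactive crosslink viewers: a
#' crosslink is kept iff its topology flag is enabled and its status flag
#' is enabled; a missing link is kept when its topology flag is enabled and
#' at least one status flag is enabled. Counts are recomputed over the
#' filtered tables.
#'
#' @param report an \code{xl_report}.
#' @param show_satisfied,show_violated,show_intra,show_inter,show_monolinks
#'   logical display flags, all on by default.
#' @return a filtered \code{xl_report}.
#' @export
filter_report <- function(report, show_satisfied = TRUE,
                          show_violated = TRUE, show_intra = TRUE,
                          show_inter = TRUE, show_monolinks = TRUE) {
  stopifnot(inherits(report, "xl_report"))
  xl <- report$crosslinks
  topo_ok <- (xl$topology == "intra" & show_intra) |
    (xl$topology == "inter" & show_inter)
  status_ok <- (xl$status == "satisfied" & show_satisfied) |
    (xl$status == "violated" & show_violated) |
    (xl$status == "missing" & (show_satisfied | show_violated))
  ml <- report$monolinks
  if (!show_monolinks) ml <- ml[0, , drop = FALSE]
  new_xl_report(report$config, xl[topo_ok & status_ok, , drop = FALSE],
                ml, report$structure_name)
}

#' @export
print.xl_report <- function(x, ...) {
  cat(format_summary(x), sep = "\n")
  invisible(x)
}

format_summary <- function(report) {
  n <- report$counts
  c(sprintf("crosslink map: %s (threshold %.1f A)",
            report$structure_name, report$config$threshold_angstrom),
    sprintf("  crosslinks total:      %d", n$n_total),
    sprintf("  displayable:           %d", n$n_displayable),
    sprintf("  satisfied:             %d", n$n_satisfied),
    sprintf("  violated:              %d", n$n_violated),
    sprintf("  missing residues:      %d", n$n_missing),
    sprintf("  intra-chain:           %d", n$n_intra),
    sprintf("  inter-chain:           %d", n$n_inter),
    sprintf("  mono-links:            %d (%d missing)",
            n$n_monolinks, n$n_monolinks_missing))
}
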