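#' Style options for generated molecular-graphics scripts
#'
#' Defaults follow the common XL-MS convention: satisfied crosslinks blue,
#' violated red; mono-link spheres green. Colors may be any name or RGB
#' spec the graphics program resolves.
#'
#' @param color_satisfied,color_violated,color_monolink color names.
#' @param dash_width,dash_gap dash geometry of crosslink lines.
#' @param sphere_scale radius scale of mono-link spheres.
#' @param object_prefix prefix used by \code{\link{object_name}}.
#' @return an object of class \code{render_style}.
#' @export
render_style <- function(color_satisfied = "blue", color_violated = "red",
                         color_monolink = "green", dash_width = 2.5,
                         dash_gap = 0.5, sphere_scale = 0.5,
                         object_prefix = "xl") {
  stopifnot(is.numeric(dash_width), dash_width > 0,
            is.numeric(dash_gap), dash_gap >= 0,
            is.numeric(sphere_scale), sphere_scale > 0,
            nzchar(color_satisfied), nzchar(color_violated),
            nzchar(color_monolink))
  structure(list(color_satisfied = color_satisfied,
                 color_violated = color_violated,
                 color_monolink = color_monolink,
                 dash_width = dash_width, dash_gap = dash_gap,
                 sphere_scale = sphere_scale,
                 object_prefix = object_prefix),
            class = "render_style")
}

#' Graphics object name for a crosslink or mono-link
#'
#' Each link is drawn as a separately named object so it can be shown or
#' hidden individually. A crosslink is named
#' \code{{prefix}_{res1}_{chain1}_{res2}_{chain2}} using the orientation
#' from the input file; a mono-link (omit \code{res_2}/\code{chain_2}) is
#' named \code{{prefix}ml_{res}_{chain}}. Characters outside
#' \code{[A-Za-z0-9_]} in chain IDs are replaced by \code{_} with a
#' warning.
#'
#' @param res_1,chain_1 first (or only) endpoint; vectorized.
#' @param res_2,chain_2 second endpoint, or NULL for a mono-link.
#' @param prefix object-name prefix.
#' @return character vector of object names.
#' @export
object_name <- function(res_1, chain_1, res_2 = NULL, chain_2 = NULL,
                        prefix = "xl") {
  san <- function(x) {
    bad <- grepl("[^A-Za-z0-9_]", x)
    if (any(bad)) {
      warning("sanitizing chain identifier(s) for object naming: ",
              paste(unique(x[bad]), collapse = ", "), call. = FALSE)
      x <- gsub("[^A-Za-z0-9_]", "_", x)
    }
    x
  }
  if (is.null(res_2)) {
    if (length(res_1) == 0L) return(character())
    paste0(prefix, "ml_", res_1, "_", san(chain_1))
  } else {
    if (length(res_1) == 0L) return(character())
    paste0(prefix, "_", res_1, "_", san(chain_1), "_",
           res_2, "_", san(chain_2))
  }
}

#' Build a PyMOL command script for a mapping report
#'
#' Emits plain-text commands loadable into PyMOL v2: each displayable
#' crosslink becomes a named dashed distance object between the two
#' C-alpha selections (\code{/object//chain/resno/CA}) with its distance
#' label hidden, colored by satisfaction status; each present mono-link
#' becomes a sphere at its C-alpha. Links whose residues are absent from
#' the structure produce a comment line only. Output is deterministic:
#' identical inputs yield byte-identical scripts.
#'
#' @param report an \code{\link{map_dataset}} (optionally
#'   \code{\link{filter_report}}-ed) result.
#' @param structure_object name of the structure object already loaded in
#'   the graphics session, typically the file stem
#'   (\code{report$structure_name}).
#' @param style a \code{\link{render_style}}.
#' @param path optional output file for the script.
#' @return character vector of script lines, invisibly when \code{path} is
#'   set.
#' @export
build_pml_script <- function(report, structure_object = report$structure_name,
                             style = render_style(), path = NULL) {
  stopifnot(inherits(report, "xl_report"), inherits(style, "render_style"))
  if (!nzchar(structure_object))
    stop("'structure_object' must name the loaded structure")
  sel <- function(chain, resno)
    sprintf("/%s//%s/%d/CA", structure_object, chain, resno)
  xl <- report$crosslinks
  ml <- report$monolinks
  n <- report$counts

  lines <- c(
    sprintf("# crosslink map for %s", report$structure_name),
    sprintf("# threshold %.1f A: %d satisfied, %d violated, %d missing; %d mono-link(s)",
            report$config$threshold_angstrom, n$n_satisfied, n$n_violated,
            n$n_missing, n$n_monolinks),
    sprintf("set dash_width, %s", format(style$dash_width)),
    sprintf("set dash_gap, %s", format(style$dash_gap)))

  for (i in seq_len(nrow(xl))) {
    if (xl$status[i] == "missing") {
      lines <- c(lines, sprintf("# not shown (missing residue %s): %s",
                                xl$absent_endpoints[i], xl$object_name[i]))
      next
    }
    col <- if (xl$status[i] == "satisfied") style$color_satisfied else
      style$color_violated
    lines <- c(lines,
      sprintf("distance %s, %s, %s", xl$object_name[i],
              sel(xl$chain_1[i], xl$res_1[i]),
              sel(xl$chain_2[i], xl$res_2[i])),
      sprintf("color %s, %s", col, xl$object_name[i]),
      sprintf("hide labels, %s", xl$object_name[i]))
  }
  for (i in seq_len(nrow(ml))) {
    if (!ml$present[i]) {
      lines <- c(lines, sprintf("# not shown (missing residue %s/%d): %s",
                                ml$chain[i], ml$res[i], ml$object_name[i]))
      next
    }
    s <- sel(ml$chain[i], ml$res[i])
    lines <- c(lines,
      sprintf("show spheres, %s", s),
      sprintf("set sphere_scale, %s, %s", format(style$sphere_scale), s),
      sprintf("color %s, %s", style$color_monolink, s))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
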