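# Test helpers: random fixture generation and a brute-force oracle that
# re-reads fixture files with its own minimal parsers, independent of the
# package implementation.

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- independent fixed-column PDB C-alpha reader (oracle side) -----------
oracle_read_ca <- function(pdb_lines) {
  rec <- pdb_lines[startsWith(pdb_lines, "ATOM") |
                   startsWith(pdb_lines, "HETATM")]
  keep <- trimws(substr(rec, 13, 16)) == "CA"
  rec <- rec[keep]
  data.frame(chain = substr(rec, 22, 22),
             resno = as.integer(trimws(substr(rec, 23, 26))),
             x = as.numeric(substr(rec, 31, 38)),
             y = as.numeric(substr(rec, 39, 46)),
             z = as.numeric(substr(rec, 47, 54)),
             stringsAsFactors = FALSE)
}

# -- independent pipe-delimited list reader (oracle side) ----------------
oracle_read_links <- function(xl_lines) {
  xl_lines <- trimws(xl_lines)
  xl_lines <- xl_lines[nzchar(xl_lines) & !startsWith(xl_lines, "#")]
  parts <- strsplit(sub("\\|$", "", xl_lines), "|", fixed = TRUE)
  is_xl <- lengths(parts) == 4L
  list(
    xl = do.call(rbind, lapply(parts[is_xl], function(f)
      data.frame(chain_1 = f[2], res_1 = as.integer(f[1]),
                 chain_2 = f[4], res_2 = as.integer(f[3]),
                 stringsAsFactors = FALSE))),
    mono = do.call(rbind, lapply(parts[!is_xl], function(f)
      data.frame(chain = f[2], res = as.integer(f[1]),
                 stringsAsFactors = FALSE))))
}

# -- brute-force mapping over fixture files (oracle side) ----------------
# loops over links, looks up C-alphas by direct subset, classifies with
# plain comparisons; deduplicates on an order-independent key the same way
# a human would when comparing lists by hand
oracle_map <- function(pdb_lines, xl_lines, threshold) {
  ca <- oracle_read_ca(pdb_lines)
  links <- oracle_read_links(xl_lines)
  xl <- links$xl
  res <- list(distance = numeric(), status = character(),
              topology = character())
  seen <- character()
  if (!is.null(xl)) {
    for (i in seq_len(nrow(xl))) {
      ends <- sort(c(paste0(xl$chain_1[i], "/", xl$res_1[i]),
                     paste0(xl$chain_2[i], "/", xl$res_2[i])))
      key <- paste(ends, collapse = "--")
      if (key %in% seen || ends[1] == ends[2]) next
      seen <- c(seen, key)
      p <- ca[ca$chain == xl$chain_1[i] & ca$resno == xl$res_1[i], ]
      q <- ca[ca$chain == xl$chain_2[i] & ca$resno == xl$res_2[i], ]
      if (nrow(p) == 0 || nrow(q) == 0) {
        res$distance <- c(res$distance, NA_real_)
        res$status <- c(res$status, "missing")
      } else {
        d <- sqrt((p$x - q$x)^2 + (p$y - q$y)^2 + (p$z - q$z)^2)
        res$distance <- c(res$distance, d)
        res$status <- c(res$status,
                        if (d > threshold) "violated" else "satisfied")
      }
      res$topology <- c(res$topology,
                        if (xl$chain_1[i] == xl$chain_2[i]) "intra"
                        else "inter")
    }
  }
  mono_present <- logical()
  if (!is.null(links$mono)) {
    mono <- links$mono[!duplicated(paste0(links$mono$chain, "/",
                                          links$mono$res)), ]
    for (i in seq_len(nrow(mono)))
      mono_present <- c(mono_present,
                        nrow(ca[ca$chain == mono$chain[i] &
                                ca$resno == mono$res[i], ]) > 0)
  }
  list(distance = res$distance, status = res$status,
       topology = res$topology, mono_present = mono_present,
       counts = list(n_total = length(res$status),
                     n_satisfied = sum(res$status == "satisfied"),
                     n_violated = sum(res$status == "violated"),
                     n_missing = sum(res$status == "missing"),
                     n_intra = sum(res$topology == "intra"),
                     n_inter = sum(res$topology == "inter"),
                     n_monolinks = length(mono_present),
                     n_monolinks_missing = sum(!mono_present)))
}

# -- random fixture generation (package-side inputs) ---------------------
random_trace_spec <- function() {
  n_chains <- sample(1:3, 1)
  ids <- LETTERS[seq_len(n_chains)]
  sizes <- sample(3:20, n_chains, replace = TRUE)
  names(sizes) <- ids
  # spacings exact at 3 decimals so closed-form expectations are exact
  trace_spec(sizes,
             spacing = sample(c(3.8, 5, 7.25, 10), 1),
             chain_offset = sample(c(20, 30, 50), 1))
}

random_links <- function(spec, n = 10, p_missing = 0.2, p_mono = 0.2) {
  ids <- names(spec$chains)
  pick <- function() {
    ch <- sample(ids, 1)
    max_r <- spec$chains[ch]
    r <- if (stats::runif(1) < p_missing) max_r + sample(1:50, 1)
         else sample(seq_len(max_r), 1)
    c(ch, r)
  }
  rows <- lapply(seq_len(n), function(i) {
    a <- pick()
    if (stats::runif(1) < p_mono)
      return(data.frame(res_1 = as.integer(a[2]), chain_1 = a[1],
                        res_2 = NA_integer_, chain_2 = NA_character_,
                        stringsAsFactors = FALSE))
    repeat {
      b <- pick()
      if (!(a[1] == b[1] && a[2] == b[2])) break
    }
    data.frame(res_1 = as.integer(a[2]), chain_1 = a[1],
               res_2 = as.integer(b[2]), chain_2 = b[1],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# standard 4-link fixture used across modules: 2 satisfied, 1 violated,
# 1 missing at threshold 27 with 10 A spacing
demo_fixture <- function(dir = tempfile("fx")) {
  dir.create(dir, showWarnings = FALSE)
  spec <- trace_spec(c(A = 10, B = 5), spacing = 10)
  pdb <- file.path(dir, "demo.pdb")
  xlf <- file.path(dir, "demo_links.txt")
  make_linear_ca_trace(spec, pdb)
  make_xl_fixture(data.frame(
    res_1 = c(1L, 3L, 1L, 1L, 2L, 99L),
    chain_1 = c("A", "A", "A", "A", "B", "B"),
    res_2 = c(3L, 5L, 6L, 99L, NA, NA),
    chain_2 = c("A", "A", "A", "A", NA, NA)), spec, xlf)
  list(spec = spec, pdb = pdb, xlf = xlf)
}
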