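#' Construct a single SNP fragment
#'
#' A SNP fragment is the projection of one sequenced DNA fragment (or one
#' barcoded read cluster) onto the heterozygous sites it overlaps: a sparse
#' map from 1-based site index to a binary allele code.  Sites where the
#' fragment is unaligned, gapped or carries a third allele are simply absent.
#'
#' @param id fragment identifier (character scalar).
#' @param sites integer vector of distinct 1-based site indices.
#' @param alleles integer vector of alleles in `{0, 1}`, parallel to `sites`.
#' @return An object of class `snp_fragment` with fields `id`, `sites`
#'   (sorted) and `alleles`.
#' @seealso [fragment_set()], [read_fragments()]
#' @export
snp_fragment <- function(id, sites, alleles) {
  sites <- as.integer(sites)
  alleles <- as.integer(alleles)
  if (length(sites) != length(alleles))
    stop("'sites' and 'alleles' must have the same length")
  if (length(sites) && (anyNA(sites) || any(sites < 1L)))
    stop("site indices must be integers >= 1")
  if (anyDuplicated(sites))
    stop("duplicate site index in fragment '", id, "'")
  if (length(alleles) && !all(alleles %in% c(0L, 1L)))
    stop("alleles must be 0 or 1")
  o <- order(sites)
  structure(list(id = as.character(id), sites = sites[o], alleles = alleles[o]),
            class = "snp_fragment")
}

#' @export
print.snp_fragment <- function(x, ...) {
  cat("<snp_fragment> ", x$id, ": ", length(x$sites), " sites [",
      if (length(x$sites)) paste0(min(x$sites), "-", max(x$sites)) else "",
      "]\n", sep = "")
  invisible(x)
}

#' Build an indexed set of SNP fragments
#'
#' Collects fragments into the container used by all downstream operations.
#' Fragments spanning fewer than two heterozygous sites carry no phase
#' information and are dropped here; the number dropped is kept in the
#' `n_dropped` field.  Internally the set stores, besides the fragment list,
#' a flat (entry-per-allele) representation used by the likelihood and VBEM
#' code.
#'
#' @param fragments list of [snp_fragment()] objects.
#' @param n_sites total number of heterozygous sites `M`; defaults to the
#'   largest spanned index.  Must be at least that index if supplied.
#' @return An object of class `fragment_set` with fields `fragments`,
#'   `n_sites`, `n_frag`, `n_dropped`, span endpoints `first`/`last`, and the
#'   flat arrays `frag`, `site`, `allele`.
#' @export
fragment_set <- function(fragments, n_sites = NULL) {
  if (!is.list(fragments))
    stop("'fragments' must be a list of snp_fragment objects")
  keep <- vapply(fragments, function(f) length(f$sites) >= 2L, logical(1))
  n_dropped <- sum(!keep)
  fragments <- fragments[keep]
  n_frag <- length(fragments)
  lens <- vapply(fragments, function(f) length(f$sites), integer(1))
  site <- unlist(lapply(fragments, `[[`, "sites"), use.names = FALSE)
  allele <- unlist(lapply(fragments, `[[`, "alleles"), use.names = FALSE)
  frag <- rep.int(seq_len(n_frag), lens)
  max_site <- if (length(site)) max(site) else 0L
  if (is.null(n_sites)) {
    n_sites <- max_site
  } else {
    n_sites <- as.integer(n_sites)
    if (n_sites < max_site)
      stop("n_sites (", n_sites, ") is smaller than the largest spanned site (",
           max_site, ")")
  }
  structure(list(
    fragments = fragments,
    n_sites = as.integer(n_sites),
    n_frag = n_frag,
    n_dropped = n_dropped,
    first = if (n_frag) vapply(fragments, function(f) f$sites[1L], integer(1)) else integer(0),
    last = if (n_frag) vapply(fragments, function(f) f$sites[length(f$sites)], integer(1)) else integer(0),
    frag = as.integer(frag),
    site = as.integer(site),
    allele = as.integer(allele)
  ), class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("<fragment_set> ", x$n_frag, " fragments over ", x$n_sites,
      " sites (", length(x$site), " allele calls",
      if (x$n_dropped) paste0("; ", x$n_dropped, " single-site fragments dropped"),
      ")\n", sep = "")
  invisible(x)
}

# subset a fragment_set by fragment indices, keeping n_sites
fs_subset <- function(fs, idx) {
  out <- fragment_set(fs$fragments[idx], n_sites = fs$n_sites)
  out$n_dropped <- fs$n_dropped
  out
}

#' Fragments covering a site boundary
#'
#' A fragment covers site `j` when it spans sites on both sides of the cut
#' between `j - 1` and `j`, i.e. it has spanned (possibly non-consecutive)
#' sites `j1 < j <= j2`.  These are exactly the fragments whose likelihood
#' changes when the haplotype labels are swapped from `j` onwards, so they
#' are the fragments that determine the connectivity at `j`.
#'
#' @param fs a [fragment_set()].
#' @param j site index, `1 <= j <= fs$n_sites`.
#' @return list of `snp_fragment` objects covering `j` (empty for `j = 1`).
#' @export
covering_fragments <- function(fs, j) {
  j <- as.integer(j)
  if (length(j) != 1L || is.na(j) || j < 1L || j > fs$n_sites)
    stop("'j' must be a single site index in 1..", fs$n_sites)
  fs$fragments[covering_index(fs, j)]
}

# integer indices of fragments covering boundary j
covering_index <- function(fs, j) {
  which(fs$first < j & j <= fs$last)
}

#' Connected components of the co-spanning site graph
#'
#' Sites are nodes; two sites are joined when at least one fragment spans
#' both.  Components with a single site cannot be phased relative to
#' anything and are discarded.  Components need not be contiguous in site
#' coordinates: fragment sets like `{1,4,5}` and `{2,3}` interleave.
#'
#' @param fs a [fragment_set()].
#' @return list of strictly increasing integer vectors of site indices,
#'   ordered by their smallest site.
#' @export
connected_components <- function(fs) {
  if (fs$n_frag == 0L) return(list())
  # consecutive spanned sites per fragment give the same components as all
  # co-spanned pairs
  not_last <- fs$frag == c(fs$frag[-1L], 0L)
  from <- fs$site[not_last]
  to <- fs$site[c(FALSE, not_last[-length(not_last)])]
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  cmp <- igraph::components(g)
  verts <- as.integer(igraph::V(g))
  comps <- split(verts, cmp$membership)
  comps <- comps[vapply(comps, length, integer(1)) >= 2L]
  comps <- lapply(unname(comps), sort)
  comps[order(vapply(comps, min, integer(1)))]
}

#' Read SNP fragments from a file
#'
#' Two plain-text dialects are supported.  The `hapcut` dialect has one
#' fragment per line: `<n_blocks> <id> <start1> <alleles1> ... <startK>
#' <allelesK>` where each block is a run of consecutive sites with its
#' 1-based start; a trailing quality string, if present, is ignored.  The
#' `matrix` dialect has one row per fragment made of characters `0`, `1`
#' and `-` (site = column index).
#'
#' @param path file to read.
#' @param dialect `"hapcut"` (default) or `"matrix"`.
#' @param n_sites optional total site count `M` (>= largest spanned index).
#' @return A [fragment_set()]; fragments spanning fewer than two sites are
#'   dropped and counted in its `n_dropped` field.
#' @export
read_fragments <- function(path, dialect = c("hapcut", "matrix"),
                           n_sites = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  frags <- if (dialect == "hapcut") {
    lapply(seq_along(lines), function(i) parse_hapcut_line(lines[[i]], i))
  } else {
    # matrix rows fix the site range through their width
    if (is.null(n_sites) && length(lines)) n_sites <- max(nchar(trimws(lines)))
    lapply(seq_along(lines), function(i) parse_matrix_line(lines[[i]], i))
  }
  fragment_set(frags, n_sites = n_sites)
}

parse_hapcut_line <- function(line, lineno) {
  tok <- strsplit(trimws(line), "[[:space:]]+")[[1]]
  bad <- function(...) stop("line ", lineno, ": ", ..., call. = FALSE)
  if (length(tok) < 4L) bad("expected at least 4 fields")
  nb <- suppressWarnings(as.integer(tok[1L]))
  if (is.na(nb) || nb < 1L) bad("invalid block count '", tok[1L], "'")
  if (length(tok) < 2L + 2L * nb)
    bad("expected ", nb, " (start, alleles) blocks")
  id <- tok[2L]
  sites <- integer(0)
  alleles <- integer(0)
  for (b in seq_len(nb)) {
    start <- suppressWarnings(as.integer(tok[2L * b + 1L]))
    if (is.na(start) || start < 1L) bad("invalid block start '", tok[2L * b + 1L], "'")
    chars <- strsplit(tok[2L * b + 2L], "")[[1]]
    if (!length(chars) || !all(chars %in% c("0", "1")))
      bad("allele string must be over {0,1}")
    sites <- c(sites, start + seq_along(chars) - 1L)
    alleles <- c(alleles, as.integer(chars))
  }
  if (anyDuplicated(sites)) bad("duplicate site in fragment '", id, "'")
  snp_fragment(id, sites, alleles)
}

parse_matrix_line <- function(line, lineno) {
  chars <- strsplit(trimws(line), "")[[1]]
  if (!all(chars %in% c("0", "1", "-")))
    stop("line ", lineno, ": characters must be 0, 1 or -", call. = FALSE)
  sites <- which(chars != "-")
  snp_fragment(paste0("row", lineno), sites, as.integer(chars[sites]))
}

#' Write SNP fragments to a file
#'
#' Mirrors [read_fragments()] bit-exactly for round-trips (the `matrix`
#' dialect pads rows to `fs$n_sites` columns).
#'
#' @param fs a [fragment_set()].
#' @param path output file.
#' @param dialect `"hapcut"` or `"matrix"`.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fs, path, dialect = c("hapcut", "matrix")) {
  dialect <- match.arg(dialect)
  lines <- if (dialect == "hapcut") {
    vapply(fs$fragments, function(f) {
      brk <- c(0L, which(diff(f$sites) != 1L), length(f$sites))
      blocks <- lapply(seq_len(length(brk) - 1L), function(k) {
        idx <- (brk[k] + 1L):brk[k + 1L]
        c(f$sites[idx[1L]], paste(f$alleles[idx], collapse = ""))
      })
      paste(c(length(blocks), f$id, unlist(blocks)), collapse = " ")
    }, character(1))
  } else {
    vapply(fs$fragments, function(f) {
      row <- rep("-", fs$n_sites)
      row[f$sites] <- as.character(f$alleles)
      paste(row, collapse = "")
    }, character(1))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read or write a known-phase file
#'
#' The phase file records the allele of haplotype 0 at each phased site,
#' one `"<site> <allele>"` pair per line (haplotype 1 is the complement).
#' The in-memory representation of a phase vector throughout the package is
#' an integer vector of haplotype-0 alleles indexed by site, with `NA` at
#' unphased sites; the globally switched vector `1 - phase` is an equivalent
#' phasing.
#'
#' @param path file to read or write.
#' @param n_sites total site count; defaults to the largest phased index.
#' @return `read_phase()` returns the phase vector; `write_phase()` returns
#'   `path` invisibly.
#' @export
read_phase <- function(path, n_sites = NULL) {
  tab <- utils::read.table(path, col.names = c("site", "allele"),
                           colClasses = "integer")
  if (any(tab$site < 1L) || !all(tab$allele %in% c(0L, 1L)))
    stop("phase file must contain 1-based sites and alleles in {0,1}")
  if (anyDuplicated(tab$site)) stop("duplicate site in phase file")
  if (is.null(n_sites)) n_sites <- max(tab$site)
  phase <- rep(NA_integer_, n_sites)
  phase[tab$site] <- tab$allele
  phase
}

#' @rdname read_phase
#' @param phase integer phase vector (haplotype-0 alleles, `NA` = unphased).
#' @export
write_phase <- function(phase, path) {
  idx <- which(!is.na(phase))
  writeLines(paste(idx, phase[idx]), path)
  invisible(path)
}
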