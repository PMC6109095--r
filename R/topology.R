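#' Protein topology model for Nav1.5
#'
#' A `protein_topology` describes the channel protein as an ordered list of
#' regions tiling residues `1..length`: the two termini, six transmembrane
#' segments per domain (S1-S6, with S4 the voltage sensor), the short
#' intra-domain linkers between segments, and the three large cytoplasmic
#' inter-domain linkers (L12, L23, L34). Every region carries a membrane
#' side: cytoplasmic, transmembrane or extracellular.
#'
#' @param regions data.frame with columns `name`, `kind`, `domain`,
#'   `segment`, `start`, `end`, `side`. `kind` is one of `terminus`,
#'   `segment`, `segment-linker`, `domain-linker`.
#' @param length protein length in residues; defaults to `max(regions$end)`.
#' @return An object of class `protein_topology`.
#' @export
protein_topology <- function(regions, length = max(regions$end)) {
  required <- c("name", "kind", "domain", "segment", "start", "end", "side")
  missing <- setdiff(required, names(regions))
  if (length(missing) > 0L) {
    stop("topology table is missing columns: ", paste(missing, collapse = ", "))
  }
  regions <- regions[order(regions$start), required, drop = FALSE]
  regions$voltage_sensing <- regions$kind == "segment" & regions$segment == 4L
  obj <- structure(
    list(length = as.integer(length), regions = regions),
    class = "protein_topology"
  )
  obj
}

#' Load a topology configuration file
#'
#' Reads the tab-separated region table (columns `name`, `kind`, `domain`,
#' `segment`, `start`, `end`, `side`; `#` comments allowed) and validates it.
#' The file shipped with the package describes the 2016-residue SCN5A
#' isoform 1 protein; alternative annotation sets are drop-in replacements.
#'
#' @param path path to a topology TSV; default is the shipped Nav1.5 model.
#' @param strict if `TRUE` (default), invalid topologies are rejected.
#' @return A validated `protein_topology`.
#' @export
load_topology <- function(path = NULL, strict = TRUE) {
  if (is.null(path)) {
    path <- system.file("extdata", "scn5a_topology.tsv", package = "navvar")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("topology file not found: ", path)
  }
  regions <- utils::read.delim(path, comment.char = "#",
                               stringsAsFactors = FALSE)
  topo <- protein_topology(regions)
  if (strict) {
    violations <- validate_topology(topo)
    if (length(violations) > 0L) {
      stop("invalid topology file '", path, "':\n  ",
           paste(violations, collapse = "\n  "))
    }
  }
  topo
}

#' Check topology invariants
#'
#' Verifies that the regions tile `1..length` without gaps or overlaps, that
#' the first and last regions are the N- and C-terminus, that there are
#' exactly four domains of six segments and three inter-domain linkers, and
#' that transmembrane segments are the only regions on the transmembrane
#' side. Violations are reported, not thrown.
#'
#' @param topology a `protein_topology`.
#' @return Character vector of violation messages; empty if valid.
#' @export
validate_topology <- function(topology) {
  r <- topology$regions
  out <- character(0)
  bad <- r$start > r$end
  if (any(bad)) {
    out <- c(out, paste0("region '", r$name[bad], "' has start > end"))
  }
  if (r$start[1L] != 1L) {
    out <- c(out, "gap: first region does not start at residue 1")
  }
  if (r$end[nrow(r)] != topology$length) {
    out <- c(out, sprintf("gap: last region ends at %d, protein length is %d",
                          r$end[nrow(r)], topology$length))
  }
  if (nrow(r) > 1L) {
    step <- r$start[-1L] - r$end[-nrow(r)]
    gaps <- which(step > 1L)
    for (i in gaps) {
      out <- c(out, sprintf("gap between '%s' and '%s' (residues %d-%d)",
                            r$name[i], r$name[i + 1L],
                            r$end[i] + 1L, r$start[i + 1L] - 1L))
    }
    overlaps <- which(step < 1L)
    for (i in overlaps) {
      out <- c(out, sprintf("overlap between '%s' and '%s'",
                            r$name[i], r$name[i + 1L]))
    }
  }
  if (r$kind[1L] != "terminus") out <- c(out, "first region is not a terminus")
  if (r$kind[nrow(r)] != "terminus") out <- c(out, "last region is not a terminus")
  seg <- r[r$kind == "segment", ]
  if (!identical(sort(unique(seg$domain)), 1:4)) {
    out <- c(out, "expected segments in exactly 4 domains")
  } else {
    for (d in 1:4) {
      s <- sort(seg$segment[seg$domain == d])
      if (!identical(s, 1:6)) {
        out <- c(out, sprintf("domain %d does not have segments 1..6", d))
      }
    }
  }
  if (sum(r$kind == "domain-linker") != 3L) {
    out <- c(out, "expected exactly 3 inter-domain linkers")
  }
  tm_mismatch <- xor(r$kind == "segment", r$side == "transmembrane")
  if (any(tm_mismatch)) {
    out <- c(out, paste0("region '", r$name[tm_mismatch],
                         "' violates segment <-> transmembrane pairing"))
  }
  out
}

#' @export
print.protein_topology <- function(x, ...) {
  r <- x$regions
  cat(sprintf("protein_topology: %d residues, %d regions\n", x$length, nrow(r)))
  cat(sprintf("  %d segments, %d segment linkers, %d domain linkers, %d termini\n",
              sum(r$kind == "segment"), sum(r$kind == "segment-linker"),
              sum(r$kind == "domain-linker"), sum(r$kind == "terminus")))
  invisible(x)
}

check_positions <- function(topology, position) {
  position <- as.integer(position)
  bad <- is.na(position) | position < 1L | position > topology$length
  if (any(bad)) {
    stop("position out of range 1..", topology$length, ": ",
         paste(utils::head(position[bad], 5L), collapse = ", "))
  }
  position
}

region_index_of <- function(topology, position) {
  r <- topology$regions
  findInterval(position, r$start)
}

#' Region containing a residue
#'
#' @param topology a `protein_topology`.
#' @param position residue position(s), 1-based.
#' @return One row of the region table per position.
#' @export
region_of <- function(topology, position) {
  position <- check_positions(topology, position)
  topology$regions[region_index_of(topology, position), , drop = FALSE]
}

#' Membrane side of a residue
#'
#' @inheritParams region_of
#' @return Character vector: `cytoplasmic`, `transmembrane` or `extracellular`.
#' @export
side_of <- function(topology, position) {
  region_of(topology, position)$side
}

#' Match a region class selector against the region table
#'
#' A selector matches a region when it equals the region name exactly
#' (e.g. `"L34"`, `"D1S4"`), equals the name with its domain prefix removed
#' (`"S4"` matches D1S4..D4S4, `"L56"` the four pore linkers), or equals the
#' region kind (`"domain-linker"`). Exact names win, so the inter-domain
#' linker `"L12"` is never confused with the intra-domain S1-S2 linkers.
#'
#' @keywords internal
match_region_class <- function(topology, region_class) {
  r <- topology$regions
  hits <- r$name == region_class
  if (!any(hits)) {
    stripped <- sub("^D[0-9]+", "", r$name)
    hits <- stripped == region_class
  }
  if (!any(hits)) hits <- r$kind == region_class
  if (!any(hits)) {
    stop("unknown region class: '", region_class, "'")
  }
  which(hits)
}

#' Residue-count distance from a position to a region class
#'
#' Distances are measured along the chain by counting residues, not
#' spatially: 0 for a position inside a matching region, otherwise the
#' minimum over matching regions of the absolute difference between the
#' position and the nearest boundary residue (so a residue immediately
#' adjacent to a region is at distance 1).
#'
#' @inheritParams region_of
#' @param region_class region name (`"L34"`), domain-stripped class
#'   (`"S4"` = nearest voltage sensor), or kind (`"domain-linker"`).
#' @return Integer vector of distances.
#' @export
distance_to <- function(topology, position, region_class) {
  position <- check_positions(topology, position)
  idx <- match_region_class(topology, region_class)
  r <- topology$regions[idx, , drop = FALSE]
  vapply(position, function(p) {
    inside <- p >= r$start & p <= r$end
    if (any(inside)) return(0L)
    as.integer(min(pmin(abs(p - r$start), abs(p - r$end))))
  }, integer(1))
}
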