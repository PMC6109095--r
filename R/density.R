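#' Relative mutation density per region
#'
#' The mutation density of a region is the number of unique reported
#' substitutions in it (two different replacements at one position count
#' twice) divided by the region length in residues. Subtracting the
#' gene-wide density gives the relative density: positive values mark
#' regions with more mutations than the gene-wide rate, negative values a
#' relative paucity. By construction the length-weighted relative densities
#' sum to zero.
#'
#' @param substitutions data.frame with columns `position` and `to_aa`;
#'   duplicate rows are collapsed to unique substitutions.
#' @param topology a `protein_topology`.
#' @param grouping `"region"` (every region separately), `"domain"`
#'   (termini, the four domains, the three inter-domain linkers) or
#'   `"region-class"` (S1..S6 and intra-domain linker classes pooled across
#'   domains, termini and domain linkers kept separate).
#' @return Object of class `density_report`: data.frame with columns
#'   `group`, `count`, `length`, `density`, `relative_density` and attribute
#'   `gene_density`.
#' @export
relative_density <- function(substitutions, topology,
                             grouping = c("region", "domain", "region-class")) {
  grouping <- match.arg(grouping)
  subs <- unique(substitutions[, c("position", "to_aa")])
  pos <- check_positions(topology, subs$position)
  r <- topology$regions
  group <- switch(grouping,
    "region" = r$name,
    "domain" = ifelse(r$domain > 0, paste0("D", r$domain), r$name),
    "region-class" = ifelse(r$domain > 0, sub("^D[0-9]+", "", r$name), r$name))
  reg_idx <- region_index_of(topology, pos)
  counts <- tapply(rep(1L, length(reg_idx)), factor(group[reg_idx], unique(group)),
                   sum, default = 0L)
  lengths <- tapply(r$end - r$start + 1L, factor(group, unique(group)), sum)
  gene_density <- nrow(subs) / topology$length
  out <- data.frame(
    group = unique(group),
    count = as.integer(counts[unique(group)]),
    length = as.integer(lengths[unique(group)]),
    stringsAsFactors = FALSE)
  out$density <- out$count / out$length
  out$relative_density <- out$density - gene_density
  attr(out, "gene_density") <- gene_density
  attr(out, "grouping") <- grouping
  class(out) <- c("density_report", "data.frame")
  out
}

#' @export
print.density_report <- function(x, ...) {
  cat(sprintf("density_report (%s grouping), gene-wide density %.4f\n",
              attr(x, "grouping"), attr(x, "gene_density")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Bar chart of relative mutation densities
#'
#' @param x a `density_report`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.density_report <- function(x, ...) {
  graphics::barplot(stats::setNames(x$relative_density, x$group),
                    las = 2, ylab = "relative mutation density", ...)
  graphics::abline(h = 0)
  invisible(x)
}

#' Per-region tallies of resolved outcomes
#'
#' Counts, for each region group and each outcome, the variants whose
#' resolved label is `affected`; a variant affecting several outcomes
#' contributes once to each. Optionally also tallies variants whose overall
#' status is unchanged.
#'
#' @param records resolved variant records from [resolve_variants()].
#' @param topology a `protein_topology`.
#' @param grouping as in [relative_density()].
#' @param include_unchanged add an `unchanged` column counting variants with
#'   `changed_unchanged == "unaffected"`.
#' @return Matrix: rows = region groups, columns = outcomes.
#' @export
outcome_tally <- function(records, topology,
                          grouping = c("region", "domain", "region-class"),
                          include_unchanged = FALSE) {
  grouping <- match.arg(grouping)
  r <- topology$regions
  group <- switch(grouping,
    "region" = r$name,
    "domain" = ifelse(r$domain > 0, paste0("D", r$domain), r$name),
    "region-class" = ifelse(r$domain > 0, sub("^D[0-9]+", "", r$name), r$name))
  groups <- unique(group)
  outs <- ep_outcomes()
  if (include_unchanged) outs <- c(outs, "unchanged")
  tally <- matrix(0L, length(groups), length(outs),
                  dimnames = list(groups, outs))
  if (nrow(records) == 0L) return(tally)
  pos <- check_positions(topology, records$position)
  g <- group[region_index_of(topology, pos)]
  for (o in ep_outcomes()) {
    t_o <- table(factor(g[records[[o]] == "affected"], groups))
    tally[, o] <- as.integer(t_o)
  }
  if (include_unchanged) {
    t_u <- table(factor(g[records$changed_unchanged == "unaffected"], groups))
    tally[, "unchanged"] <- as.integer(t_u)
  }
  tally
}
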