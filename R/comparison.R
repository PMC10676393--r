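#' Compare two cross-lagged networks over the same items
#'
#' An edge is counted as replicated when it is nonzero with the same sign
#' in both networks. The replication percentage is reported relative to a
#' configurable denominator: `"first"` (edges nonzero in the first
#' network; the default, not symmetric in the arguments), `"union"` (edges
#' nonzero in at least one network; symmetric), or `"either"` (the mean of
#' the two one-sided percentages; symmetric). All three are returned; the
#' `denominator` argument selects which one fills the `replication_pct`
#' field. Edge-weight correlation is the Pearson correlation over all
#' cross-lagged positions on the log-odds scale with zeros included (set
#' `jointly_nonzero = TRUE` to restrict to edges nonzero in both), and the
#' centrality correlations are over the items' in- and
#' out-expected-influence.
#'
#' @param a,b `clpn` objects over identical item sets.
#' @param denominator `"first"`, `"union"` or `"either"`.
#' @param jointly_nonzero restrict the edge-weight correlation to jointly
#'   nonzero edges?
#' @return Object of class `network_comparison` (also coercible with
#'   `as.data.frame`).
#' @export
compare_networks <- function(a, b, denominator = c("first", "union", "either"),
                             jointly_nonzero = FALSE) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(a, "clpn"), inherits(b, "clpn"))
  if (!identical(a$items, b$items)) stopf("item sets differ between networks")
  wa <- item_beta(a); wb <- item_beta(b)
  off <- row(wa) != col(wa)
  ea <- wa[off]; eb <- wb[off]  # fixed, order-stable enumeration

  both <- sum(ea != 0 & eb != 0 & sign(ea) == sign(eb))
  n_a <- sum(ea != 0); n_b <- sum(eb != 0)
  n_union <- sum(ea != 0 | eb != 0)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  repl <- c(first = pct(both, n_a), union = pct(both, n_union),
            either = mean(c(pct(both, n_a), pct(both, n_b))))

  sel <- if (jointly_nonzero) (ea != 0 & eb != 0) else rep(TRUE, length(ea))
  edge_r <- suppressWarnings(cor(ea[sel], eb[sel]))
  eia <- expected_influence(a); eib <- expected_influence(b)
  structure(list(
    network_a = attr(a, "label"), network_b = attr(b, "label"),
    replication_pct = unname(repl[denominator]),
    replication_denominator = denominator,
    replication_all = repl,
    edge_weight_r = edge_r,
    in_ei_r = suppressWarnings(cor(eia$in_ei, eib$in_ei)),
    out_ei_r = suppressWarnings(cor(eia$out_ei, eib$out_ei)),
    n_edges_a = n_a, n_edges_b = n_b, n_replicated = both
  ), class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf("Network comparison %s vs %s\n", x$network_a, x$network_b))
  cat(sprintf("  replicated edges: %d (%.1f%% of %s denominator; first %.1f%%, union %.1f%%, either %.1f%%)\n",
              x$n_replicated, x$replication_pct, x$replication_denominator,
              x$replication_all["first"], x$replication_all["union"],
              x$replication_all["either"]))
  cat(sprintf("  edge-weight r = %.3f; in-EI r = %.3f; out-EI r = %.3f\n",
              x$edge_weight_r, x$in_ei_r, x$out_ei_r))
  invisible(x)
}

#' @export
as.data.frame.network_comparison <- function(x, ...) {
  data.frame(network_a = x$network_a, network_b = x$network_b,
             replication_denominator = x$replication_denominator,
             replication_pct = x$replication_pct,
             replication_pct_first = unname(x$replication_all["first"]),
             replication_pct_union = unname(x$replication_all["union"]),
             replication_pct_either = unname(x$replication_all["either"]),
             edge_weight_r = x$edge_weight_r,
             in_ei_r = x$in_ei_r, out_ei_r = x$out_ei_r,
             n_edges_a = x$n_edges_a, n_edges_b = x$n_edges_b,
             n_replicated = x$n_replicated)
}
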