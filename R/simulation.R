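#' Run one simulation scenario
#'
#' For each replicate: generate a multi-site dataset, fit the pooled
#' pairwise-likelihood gold standard, then fit every requested comparator
#' on the same dataset and record per-coefficient estimates and relative
#' bias `(estimate - gold) / gold`.  Replicates in which the gold fit
#' fails are dropped and counted; more than 20% failures aborts, signaling
#' a degenerate scenario configuration.
#'
#' @param config A [scenario_config()].
#' @param n_replicates Number of replicates (default 100).
#' @param methods Character subset of `c("meta", "dclr")`.
#' @param dclr_args Extra arguments for [fit_dclr()] (e.g. `order`,
#'   `lead_selection`; default is the all-sites synthesis with the
#'   second-order surrogate).
#' @return A `dclr_simulation` data frame with one row per replicate x
#'   method x coefficient: `replicate`, `method`, `coefficient`,
#'   `estimate`, `gold_estimate`, `true_value`, `relative_bias`,
#'   `data_fingerprint`; attributes carry the config, failure count and
#'   replicate indices.
#' @export
run_scenario <- function(config, n_replicates = 100L,
                         methods = c("meta", "dclr"),
                         dclr_args = list()) {
  stopifnot(inherits(config, "scenario_config"), n_replicates >= 1)
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  failed <- integer(0)
  coefs <- names(config$beta_true)
  for (r in seq_len(n_replicates)) {
    ms <- generate_multisite(config, replicate = r)
    fp <- data_fingerprint(ms)
    gold <- tryCatch(fit_pooled(ms), error = function(e) NULL)
    if (is.null(gold) || !gold$converged) { failed <- c(failed, r); next }

    initials <- lapply(ms$sites, function(s)
      tryCatch(emit_initial(s), error = function(e) NULL))
    initials <- Filter(Negate(is.null), initials)
    ests <- list()
    if ("meta" %in% methods)
      ests$meta <- tryCatch(
        coef(fit_meta(lapply(initials, initial_as_fit))),
        error = function(e) rep(NA_real_, length(coefs)))
    if ("dclr" %in% methods) {
      anchor <- initial_average(initials)
      derivs <- lapply(ms$sites, emit_derivatives, anchor = anchor)
      ests$dclr <- tryCatch(
        coef(do.call(fit_dclr, c(list(ms$sites,
                                      .payloads = list(initial = initials,
                                                       anchor = anchor,
                                                       derivatives = derivs)),
                                 dclr_args))),
        error = function(e) rep(NA_real_, length(coefs)))
    }
    for (m in names(ests)) {
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, method = m, coefficient = coefs,
        estimate = as.numeric(ests[[m]]),
        gold_estimate = as.numeric(gold$beta_hat),
        true_value = as.numeric(config$beta_true),
        relative_bias = (as.numeric(ests[[m]]) -
                           as.numeric(gold$beta_hat)) /
          as.numeric(gold$beta_hat),
        data_fingerprint = fp,
        stringsAsFactors = FALSE)
    }
  }
  if (length(failed) > 0.2 * n_replicates)
    stop(sprintf(
      "gold-standard fit failed in %d/%d replicates: degenerate scenario",
      length(failed), n_replicates))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("dclr_simulation", "data.frame"),
            config = config, n_replicates = n_replicates,
            failed_replicates = failed, methods = methods)
}

# payload -> minimal fit object usable by fit_meta
initial_as_fit <- function(pl) {
  if (!isTRUE(pl$estimable)) return(NULL)
  p <- length(pl$beta_hat)
  new_fit_result("local", pl$beta_hat, diag(pl$var_diag, p),
                 converged = TRUE, n_iterations = NA_integer_,
                 diagnostics = list(site_id = pl$site_id, n_k = pl$n_k,
                                    d_k = pl$d_k))
}

# cheap deterministic dataset fingerprint (sums rendered exactly)
data_fingerprint <- function(ms) {
  v <- vapply(ms$sites, function(s)
    sum(s$y) + sum(s$X) + length(s$y), numeric(1))
  paste(sprintf("%a", c(sum(v), sum(v^2))), collapse = "|")
}

#' Summarize a simulation run
#'
#' Per method and coefficient: mean, median and SD of relative bias, mean
#' absolute relative bias, replicate count, and — on the dCLR rows — the
#' percent reduction `100 (1 - mean|RB_dclr| / mean|RB_meta|)` relative to
#' meta-analysis (NA when the meta reference is zero).
#'
#' @param result A `dclr_simulation` from [run_scenario()].
#' @return Data frame of summary rows.
#' @export
summarize_scenario <- function(result) {
  stopifnot(inherits(result, "dclr_simulation"))
  ok <- is.finite(result$relative_bias)
  if (!any(ok)) stop("no successful replicates to summarize")
  d <- result[ok, ]
  key <- interaction(d$method, d$coefficient, drop = TRUE)
  parts <- lapply(split(d, key), function(g) data.frame(
    method = g$method[1], coefficient = g$coefficient[1],
    n_replicates = nrow(g),
    mean_rb = mean(g$relative_bias),
    median_rb = median(g$relative_bias),
    sd_rb = sd(g$relative_bias),
    mean_abs_rb = mean(abs(g$relative_bias)),
    stringsAsFactors = FALSE))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out$pct_reduction_vs_meta <- NA_real_
  if (all(c("meta", "dclr") %in% out$method)) {
    for (cf in unique(out$coefficient)) {
      m <- out$mean_abs_rb[out$method == "meta" & out$coefficient == cf]
      dd <- out$mean_abs_rb[out$method == "dclr" & out$coefficient == cf]
      if (length(m) == 1 && length(dd) == 1 && m > 0)
        out$pct_reduction_vs_meta[out$method == "dclr" &
                                    out$coefficient == cf] <-
          100 * (1 - dd / m)
    }
  }
  out
}

#' Violin plots of relative bias across scenarios
#'
#' Mirrors the standard presentation of multi-scenario relative-bias
#' results: one panel per (site count, heterogeneity) combination, site
#' prevalence medians on the x axis, one violin per method, and a dashed
#' line at zero relative bias.
#'
#' @param results A `dclr_simulation` or a list of them (one per scenario).
#' @param file Optional path; when given the figure is saved there
#'   (format from the extension).
#' @param width,height Device size in inches when `file` is given.
#' @return The ggplot object, invisibly when written to file.
#' @export
plot_violins <- function(results, file = NULL, width = 9, height = 6) {
  if (inherits(results, "dclr_simulation")) results <- list(results)
  stopifnot(length(results) >= 1)
  d <- do.call(rbind, lapply(results, function(r) {
    cfg <- attr(r, "config")
    df <- as.data.frame(r)
    if (nrow(df) == 0) stop("a scenario has no results to plot")
    df$K <- sprintf("K = %d", cfg$K)
    df$prevalence <- sprintf("median prev %.3g%%",
                             100 * cfg$prevalence_median)
    df$heterogeneity <- cfg$heterogeneity
    df
  }))
  d <- d[is.finite(d$relative_bias), ]
  if (nrow(d) == 0 || length(unique(d$method)) == 0)
    stop("no methods/replicates to plot")
  gg <- ggplot2::ggplot(
    d, ggplot2::aes(x = prevalence, y = relative_bias, fill = method)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_violin(position = ggplot2::position_dodge(width = 0.8),
                         scale = "width", trim = TRUE) +
    ggplot2::facet_grid(K ~ heterogeneity) +
    ggplot2::labs(x = NULL, y = "relative bias vs pooled gold standard",
                  fill = NULL) +
    ggplot2::theme_bw()
  if (!is.null(file)) {
    ggplot2::ggsave(file, gg, width = width, height = height)
    return(invisible(gg))
  }
  gg
}
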