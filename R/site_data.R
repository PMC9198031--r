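#' Patient-level data for one site
#'
#' Bundles a site identifier, a binary outcome vector and a covariate matrix
#' into a validated `site_data` object.  This object never leaves the site
#' in the distributed protocol; only aggregates derived from it do.
#'
#' @param site_id Character scalar naming the site.
#' @param y Binary outcome vector (each entry exactly 0 or 1).
#' @param X Numeric covariate matrix, one row per subject, no intercept
#'   column (intercepts are eliminated by pairwise conditioning, so one is
#'   neither needed nor estimable).  Columns may be continuous or 0/1 coded.
#'   Missing values are not allowed.
#' @return A `site_data` object with elements `site_id`, `y`, `X`.
#' @examples
#' site_data("A", c(1, 0, 0), cbind(x1 = c(0.2, -1, 1)))
#' @export
site_data <- function(site_id, y, X) {
  stopifnot(is.character(site_id) || is.factor(site_id), length(site_id) == 1)
  y <- as.numeric(y)
  if (length(y) < 1) stop("site '", site_id, "': needs at least one subject")
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop("site '", site_id, "': outcome must be exactly 0 or 1 with no NA")
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) != length(y))
    stop("site '", site_id, "': X has ", nrow(X), " rows but y has length ",
         length(y))
  if (ncol(X) < 1) stop("site '", site_id, "': at least one covariate required")
  if (anyNA(X))
    stop("site '", site_id, "': covariates contain missing values; ",
         "impute or drop before analysis")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  structure(list(site_id = as.character(site_id), y = y, X = X),
            class = "site_data")
}

#' @export
print.site_data <- function(x, ...) {
  cat(sprintf("<site_data '%s': n = %d (%d cases, %d controls), p = %d>\n",
              x$site_id, length(x$y), sum(x$y == 1), sum(x$y == 0),
              ncol(x$X)))
  invisible(x)
}

# cases / controls split used by every pair computation
site_split <- function(data) {
  list(Xcase = data$X[data$y == 1, , drop = FALSE],
       Xctrl = data$X[data$y == 0, , drop = FALSE])
}

# discordant pair count without building pairs
site_n_pairs <- function(data) {
  as.numeric(sum(data$y == 1)) * as.numeric(sum(data$y == 0))
}

is_site_data <- function(x) inherits(x, "site_data")

as_site_list <- function(sites) {
  if (is_site_data(sites)) return(list(sites))
  if (inherits(sites, "multisite_data")) return(sites$sites)
  stopifnot(is.list(sites), all(vapply(sites, is_site_data, logical(1))))
  sites
}
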