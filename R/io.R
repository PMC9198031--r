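#' Read a multi-site patient table
#'
#' Expects comma-separated text with a header containing `site_id`, `y`,
#' and at least one covariate column (taken in header order).  Rows are
#' grouped by `site_id` preserving first-appearance order.  `y` must be
#' exactly 0 or 1 and no value may be missing — offending rows are named
#' in the error (no imputation is attempted).
#'
#' @param path Path to a CSV file.
#' @return List of [site_data()] objects.
#' @export
read_multisite_table <- function(path) {
  if (!file.exists(path)) stop("input file '", path, "' does not exist")
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "y")
  if (!all(need %in% names(df)))
    stop("'", path, "' must contain columns site_id and y")
  covs <- setdiff(names(df), need)
  if (length(covs) < 1) stop("'", path, "' has no covariate columns")
  bad_y <- which(is.na(df$y) | !(df$y %in% c(0, 1)))
  if (length(bad_y))
    stop("non-binary outcome value in row(s) ",
         paste(head(bad_y, 5), collapse = ", "), " of '", path, "'")
  for (cv in covs) {
    if (!is.numeric(df[[cv]]))
      stop("covariate column '", cv, "' is not numeric")
    bad <- which(is.na(df[[cv]]))
    if (length(bad))
      stop("missing value in column '", cv, "', row(s) ",
           paste(head(bad, 5), collapse = ", "),
           "; impute or drop before analysis")
  }
  ids <- unique(df$site_id)
  lapply(ids, function(id) {
    sub <- df[df$site_id == id, , drop = FALSE]
    X <- as.matrix(sub[, covs, drop = FALSE])
    rownames(X) <- NULL
    site_data(as.character(id), sub$y, X)
  })
}

#' Write multi-site data as a CSV table
#'
#' Inverse of [read_multisite_table()]: columns `site_id`, `y`, then the
#' covariates.
#'
#' @param sites List of [site_data()] (or a `multisite_data`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_multisite_table <- function(sites, path) {
  sites <- as_site_list(sites)
  df <- do.call(rbind, lapply(sites, function(s)
    data.frame(site_id = s$site_id, y = s$y, s$X, check.names = FALSE,
               stringsAsFactors = FALSE)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
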