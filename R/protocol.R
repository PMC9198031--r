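# ---- payload construction -------------------------------------------------

#' Step I payload: a site's initial estimate as aggregates only
#'
#' Fits the site's own pairwise conditional logistic model and packages the
#' result for broadcast.  The payload carries only aggregate quantities —
#' coefficient vector, variance diagonal, subject and pair counts — never
#' patient rows.  A site with no discordant pairs emits `estimable = FALSE`
#' with counts only.
#'
#' @param data A [site_data()] object.
#' @param ... Passed to [fit_local()] (e.g. `ridge`).
#' @return A `dclr_initial` payload.
#' @export
emit_initial <- function(data, ...) {
  stopifnot(is_site_data(data))
  n_k <- length(data$y)
  d_k <- site_n_pairs(data)
  if (d_k < 1) {
    return(structure(list(kind = "initial", site_id = data$site_id,
                          beta_hat = NULL, var_diag = NULL,
                          n_k = n_k, d_k = d_k, estimable = FALSE),
                     class = "dclr_initial"))
  }
  fit <- fit_local(data, ...)
  structure(list(kind = "initial", site_id = data$site_id,
                 beta_hat = fit$beta_hat,
                 var_diag = if (!is.null(fit$covariance))
                   setNames(diag(fit$covariance), names(fit$beta_hat)),
                 n_k = n_k, d_k = d_k, estimable = TRUE),
            class = "dclr_initial")
}

as_initial_payload <- function(x) {
  if (inherits(x, "dclr_initial")) return(x)
  if (inherits(x, "dclr_fit")) {
    return(structure(list(kind = "initial",
                          site_id = x$diagnostics$site_id %||% NA_character_,
                          beta_hat = x$beta_hat,
                          var_diag = if (!is.null(x$covariance))
                            diag(as.matrix(x$covariance)),
                          n_k = x$diagnostics$n_k %||% NA_real_,
                          d_k = x$diagnostics$d_k %||% NA_real_,
                          estimable = all(is.finite(x$beta_hat))),
                     class = "dclr_initial"))
  }
  stop("cannot interpret object of class '", class(x)[1],
       "' as an initial payload")
}

#' Exact fingerprint of an anchor vector
#'
#' Concatenated C99 hex-float renderings of the anchor coordinates: two
#' anchors share a fingerprint if and only if they are bit-identical, which
#' binds each Step II payload to the exact anchor it was evaluated at.
#'
#' @param beta Numeric anchor vector.
#' @return Character scalar.
#' @export
anchor_fingerprint <- function(beta) {
  paste(sprintf("%a", as.numeric(beta)), collapse = ",")
}

#' Step II payload: gradient and Hessian at the shared anchor
#'
#' Evaluates the site's pairwise log-likelihood derivatives at the anchor
#' and packages the raw (unnormalized) sums together with subject and pair
#' counts, so the coordinator can apply any weight normalization.  A site
#' with no discordant pairs contributes exact zeros.
#'
#' @param data A [site_data()] object.
#' @param anchor Numeric anchor vector (the shared initial estimate).
#' @return A `dclr_derivatives` payload whose `anchor_fingerprint` binds it
#'   to `anchor`.
#' @export
emit_derivatives <- function(data, anchor) {
  stopifnot(is_site_data(data))
  anchor <- check_beta(anchor, ncol(data$X))
  ev <- pair_eval(anchor, data, 2L)
  structure(list(kind = "derivatives", site_id = data$site_id,
                 anchor_fingerprint = anchor_fingerprint(anchor),
                 gradient = ev$grad, hessian = ev$hess,
                 n_k = length(data$y), d_k = ev$d_k),
            class = "dclr_derivatives")
}

#' Validate one communication round of payloads
#'
#' Coordinator-side checks before any payload is used: every Step II
#' payload must carry the expected anchor fingerprint, a symmetric Hessian
#' and finite entries; Step I payloads must have consistent counts.  A
#' violation is a hard error naming the offending site.
#'
#' @param payloads List of `dclr_initial` or `dclr_derivatives` payloads.
#' @param expected_anchor Anchor vector the round was announced with
#'   (required when validating derivative payloads).
#' @return The validated payload list, invisibly unchanged.
#' @export
validate_round <- function(payloads, expected_anchor = NULL) {
  stopifnot(is.list(payloads), length(payloads) >= 1)
  fp <- if (!is.null(expected_anchor)) anchor_fingerprint(expected_anchor)
  for (pay in payloads) {
    id <- pay$site_id %||% "<unknown>"
    if (inherits(pay, "dclr_derivatives")) {
      if (!is.null(fp) && !identical(pay$anchor_fingerprint, fp))
        stop("site '", id, "': anchor fingerprint mismatch ",
             "(payload was evaluated at a different anchor)")
      if (anyNA(pay$gradient) || !all(is.finite(pay$gradient)))
        stop("site '", id, "': non-finite gradient entry")
      if (anyNA(pay$hessian) || !all(is.finite(pay$hessian)))
        stop("site '", id, "': non-finite Hessian entry")
      if (max(abs(pay$hessian - t(pay$hessian))) > 0)
        stop("site '", id, "': Hessian is not symmetric")
    } else if (inherits(pay, "dclr_initial")) {
      if (isTRUE(pay$estimable) &&
          (is.null(pay$beta_hat) || !all(is.finite(pay$beta_hat))))
        stop("site '", id, "': estimable payload without finite estimate")
      if (pay$d_k > floor(pay$n_k^2 / 4))
        stop("site '", id, "': impossible pair count")
    } else stop("site '", id, "': unknown payload kind")
  }
  log_info("validated round: %d payloads (%d estimable)",
           length(payloads),
           sum(vapply(payloads, function(p)
             !identical(p$estimable, FALSE), logical(1))))
  invisible(payloads)
}

# ---- sparse-cell privacy screen ------------------------------------------

#' Advisory small-cell screen before sharing aggregates
#'
#' Cross-tabulates the outcome against each binary (0/1-valued) covariate
#' and reports any cell with a count below `k_threshold`, plus the outcome
#' margin itself.  Sparse cells in shared aggregates raise re-identification
#' risk; the screen warns but never blocks — data contributors are expected
#' to review flagged cells before sending payloads.
#'
#' @param data A [site_data()] object.
#' @param k_threshold Minimum acceptable cell count (default 11, a common
#'   small-cell suppression convention).
#' @return Data frame with columns `table`, `cell`, `count`, `flagged`;
#'   zero flagged rows means the screen passed.
#' @export
sparse_cell_screen <- function(data, k_threshold = 11L) {
  stopifnot(is_site_data(data), k_threshold >= 1)
  rows <- data.frame(table = "outcome",
                     cell = c("y=0", "y=1"),
                     count = c(sum(data$y == 0), sum(data$y == 1)),
                     stringsAsFactors = FALSE)
  for (j in seq_len(ncol(data$X))) {
    xj <- data$X[, j]
    if (!all(xj %in% c(0, 1))) next
    nm <- colnames(data$X)[j]
    for (yy in 0:1) for (xx in 0:1) {
      rows <- rbind(rows, data.frame(
        table = paste0("outcome x ", nm),
        cell = sprintf("y=%d,%s=%d", yy, nm, xx),
        count = sum(data$y == yy & xj == xx),
        stringsAsFactors = FALSE))
    }
  }
  rows$flagged <- rows$count < k_threshold
  if (any(rows$flagged))
    warning("site '", data$site_id, "': ", sum(rows$flagged),
            " sparse cell(s) below k = ", k_threshold,
            "; review aggregates before sharing", call. = FALSE)
  rows
}

# ---- serialization --------------------------------------------------------

# doubles as 17-significant-digit decimal strings: round-trips bit-exactly
num_encode <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.matrix(x)) apply(x, c(1, 2), function(v) sprintf("%.17g", v))
  else sprintf("%.17g", x)
}
num_decode <- function(x, names = NULL) {
  if (is.null(x)) return(NULL)
  if (is.matrix(x)) {
    out <- apply(x, c(1, 2), as.numeric)
    dimnames(out) <- NULL
  } else out <- as.numeric(unlist(x))
  if (!is.null(names) && !is.matrix(x)) names(out) <- names
  out
}

#' Write a protocol payload to a JSON document
#'
#' One document per site per round.  Numeric fields are encoded as
#' 17-significant-digit decimal strings, which reproduce the original
#' doubles bit-exactly on any IEEE-754 platform, so the distributed
#' file-exchange deployment is byte-reproducible.
#'
#' @param payload A `dclr_initial`, `dclr_derivatives`, or `dclr_anchor`
#'   object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_payload <- function(payload, path) {
  doc <- list(format = "dclr-payload-1", kind = payload$kind,
              package_version = as.character(packageVersion("dclr")))
  body <- unclass(payload)
  for (nm in names(body)) {
    v <- body[[nm]]
    doc[[nm]] <- if (is.numeric(v) && !nm %in% c("n_k", "d_k")) {
      if (is.matrix(v)) num_encode(v)
      else list(names = names(v), values = num_encode(v))
    } else v
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a protocol payload written by [write_payload()]
#'
#' @param path Path to a payload JSON document.
#' @return The payload object with numeric fields restored bit-exactly.
#' @export
read_payload <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "dclr-payload-1"))
    stop("'", path, "' is not a dclr payload document")
  dec <- function(v) {
    if (is.list(v) && !is.null(v$values))
      num_decode(v$values, if (length(v$names)) v$names)
    else v
  }
  out <- switch(doc$kind,
    initial = structure(list(kind = "initial", site_id = doc$site_id,
                             beta_hat = dec(doc$beta_hat),
                             var_diag = dec(doc$var_diag),
                             n_k = as.numeric(doc$n_k),
                             d_k = as.numeric(doc$d_k),
                             estimable = isTRUE(doc$estimable)),
                        class = "dclr_initial"),
    derivatives = structure(list(kind = "derivatives", site_id = doc$site_id,
                                 anchor_fingerprint = doc$anchor_fingerprint,
                                 gradient = dec(doc$gradient),
                                 hessian = num_decode(as.matrix(doc$hessian)),
                                 n_k = as.numeric(doc$n_k),
                                 d_k = as.numeric(doc$d_k)),
                            class = "dclr_derivatives"),
    anchor = structure(list(kind = "anchor",
                            beta = dec(doc$beta),
                            scheme = doc$scheme,
                            anchor_fingerprint = doc$anchor_fingerprint),
                       class = "dclr_anchor"),
    stop("unknown payload kind '", doc$kind, "'"))
  out
}

make_anchor_payload <- function(beta, scheme) {
  structure(list(kind = "anchor", beta = beta, scheme = scheme,
                 anchor_fingerprint = anchor_fingerprint(beta)),
            class = "dclr_anchor")
}

# ---- logging --------------------------------------------------------------

log_info <- function(fmt, ...) {
  if (isTRUE(getOption("dclr.quiet", TRUE))) return(invisible(NULL))
  message(sprintf("[%s] dclr: %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                  sprintf(fmt, ...)))
}
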