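#' Partial least squares discriminant analysis with VIP
#'
#' Fits a PLS-DA model of a binary group label on an item matrix by
#' sequential NIPALS components: each component's weight vector maximises
#' covariance between the (centred, unit-variance scaled) items and the
#' centred 0/1 label indicator, with deflation of X and y between
#' components. Missing item entries are handled inside NIPALS by
#' pairwise-available accumulation — every inner regression sums over the
#' observed entries only — so incomplete respondents still contribute.
#'
#' Variable importance in projection for item `j` over `A` components is
#' \deqn{VIP_j = \sqrt{p \sum_a SS_a (w_{ja}/\lVert w_a \rVert)^2 / \sum_a SS_a}}
#' where `SS_a` is the label sum of squares explained by component `a` and
#' `p` the number of items; squared VIPs always sum to `p`. Items with
#' `VIP > 1` are conventionally read as of major importance to the
#' discrimination.
#'
#' @param x numeric matrix or data frame of items (respondents x items);
#'   `NA` allowed.
#' @param y binary label: logical, 0/1 numeric, or a two-level factor /
#'   character vector (first level in sort order is coded 0).
#' @param ncomp number of components to extract (default 2).
#' @param center,scale preprocessing applied to the item columns before
#'   fitting (defaults: centre and unit-variance scale, the SIMCA-style
#'   convention for questionnaire items).
#' @return an object of class `fd_plsda` with elements `weights` (p x A,
#'   unit-norm columns), `x_loadings`, `y_loadings`, `x_scores`,
#'   `ss_explained` (per-component explained label sum of squares), `vip`,
#'   `fitted` (fitted label indicator on the 0/1 scale), `preprocessing`,
#'   and the dimensions/names needed by the methods below.
#' @seealso [tidy.fd_plsda()], [glance.fd_plsda()], [autoplot.fd_plsda()]
#' @export
plsda_fit <- function(x, y, ncomp = 2, center = TRUE, scale = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) < 1L) abort("x must have at least one item column")
  y01 <- encode_binary(y)
  if (length(y01) != nrow(x)) abort("length(y) must match nrow(x)")
  if (length(unique(y01)) != 2L || min(table(y01)) < 2L) {
    abort("y must contain both classes with at least 2 respondents each",
          class = "fd_contract_error")
  }
  if (ncomp < 1) abort("ncomp must be >= 1")

  p <- ncol(x)
  items <- colnames(x) %||% paste0("item", seq_len(p))

  mu <- colMeans(x, na.rm = TRUE)
  sdv <- apply(x, 2, sd, na.rm = TRUE)
  if (any(is.na(sdv)) || (scale && any(sdv == 0))) {
    abort("each item needs at least two observed, non-constant values")
  }
  xs <- sweep(x, 2, if (center) mu else rep(0, p))
  if (scale) xs <- sweep(xs, 2, sdv, "/")
  yc <- y01 - mean(y01)
  ss_y_total <- sum(yc^2)

  W <- P <- matrix(0, p, 0)
  Tm <- matrix(0, nrow(x), 0)
  cvec <- numeric(0)
  ss <- numeric(0)
  Xd <- xs
  yd <- yc

  for (a in seq_len(ncomp)) {
    ## w_j = sum_obs x_ij y_i / sum_obs y_i^2, column-wise over observed pairs
    w <- pairwise_regress(Xd, yd, margin = 2)
    wn <- sqrt(sum(w^2))
    if (!is.finite(wn) || wn < 1e-12) {
      abort(sprintf(
        "only %d component(s) extractable (rank exhausted); lower ncomp",
        a - 1L), class = "fd_rank_error")
    }
    w <- w / wn
    ## t_i = sum_obs x_ij w_j / sum_obs w_j^2, row-wise over observed pairs
    t <- pairwise_regress(Xd, w, margin = 1)
    tt <- sum(t^2)
    if (tt < 1e-12) {
      abort(sprintf(
        "only %d component(s) extractable (rank exhausted); lower ncomp",
        a - 1L), class = "fd_rank_error")
    }
    cc <- sum(yd * t) / tt
    pl <- pairwise_regress(Xd, t, margin = 2)
    Xd <- Xd - tcrossprod(t, pl)   # NA entries stay NA
    yd <- yd - cc * t
    W <- cbind(W, w); P <- cbind(P, pl); Tm <- cbind(Tm, t)
    cvec <- c(cvec, cc)
    ss <- c(ss, cc^2 * tt)
  }

  vip <- sqrt(p * as.numeric(W^2 %*% ss) / sum(ss))
  fitted <- as.numeric(Tm %*% cvec) + mean(y01)
  dimnames(W) <- dimnames(P) <- list(items, paste0("comp", seq_len(ncomp)))
  colnames(Tm) <- paste0("comp", seq_len(ncomp))

  structure(list(
    n_components = ncomp,
    weights = W, x_loadings = P, y_loadings = cvec, x_scores = Tm,
    ss_explained = ss, r_squared_y = sum(ss) / ss_y_total,
    vip = setNames(vip, items), fitted = fitted, y = y01,
    items = items,
    preprocessing = list(center = center, scale = scale,
                         means = mu, sds = sdv)
  ), class = "fd_plsda")
}

## slope of v on u over observed entries of X, per column (margin = 2)
## or per row (margin = 1); the NIPALS missing-data convention
pairwise_regress <- function(X, v, margin) {
  obs <- !is.na(X)
  X0 <- ifelse(obs, X, 0)
  if (margin == 2) {
    num <- as.numeric(crossprod(X0, v))
    den <- as.numeric(crossprod(obs, v^2))
  } else {
    num <- as.numeric(X0 %*% v)
    den <- as.numeric(obs %*% v^2)
  }
  out <- ifelse(den > 0, num / den, 0)
  out
}

encode_binary <- function(y) {
  if (is.logical(y)) return(as.numeric(y))
  if (is.factor(y) || is.character(y)) {
    lev <- sort(unique(as.character(y)))
    if (length(lev) != 2L) {
      abort("y must have exactly two classes", class = "fd_contract_error")
    }
    return(as.numeric(as.character(y) == lev[2]))
  }
  if (!all(y %in% c(0, 1))) {
    abort("numeric y must be 0/1", class = "fd_contract_error")
  }
  as.numeric(y)
}

#' @export
print.fd_plsda <- function(x, ...) {
  cat(sprintf("PLS-DA fit: %d item(s), %d component(s), R2Y = %.3f\n",
              length(x$items), x$n_components, x$r_squared_y))
  cat("VIP:\n")
  print(round(x$vip, 3))
  invisible(x)
}

#' Tidy a PLS-DA fit into a per-item tibble
#'
#' @param x an `fd_plsda` object.
#' @param ... unused.
#' @return tibble with one row per item: VIP and per-component weights.
#' @method tidy fd_plsda
#' @export
tidy.fd_plsda <- function(x, ...) {
  out <- tibble(item = x$items, vip = as.numeric(x$vip))
  dplyr::bind_cols(out, as_tibble(x$weights))
}

#' One-row summary of a PLS-DA fit
#'
#' @param x an `fd_plsda` object.
#' @param ... unused.
#' @return tibble with `n_items`, `n_components`, `r_squared_y`.
#' @method glance fd_plsda
#' @export
glance.fd_plsda <- function(x, ...) {
  tibble(n_items = length(x$items), n_components = x$n_components,
         r_squared_y = x$r_squared_y)
}

#' VIP bar chart for a PLS-DA fit
#'
#' Items ordered by variable importance, with the conventional VIP = 1
#' reference line.
#'
#' @param object an `fd_plsda` object.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot fd_plsda
#' @export
autoplot.fd_plsda <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$item, .data$vip), y = .data$vip)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "VIP",
                  title = "Variable importance in projection") +
    ggplot2::theme_minimal()
}
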