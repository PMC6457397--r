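#' Brownian-motion covariance matrix of a tree
#'
#' `C[i, j]` is the root-to-MRCA path length of species i and j (shared
#' evolutionary history under Brownian motion); the diagonal holds
#' root-to-leaf depths.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param species Leaf labels defining row/column order.
#' @return Symmetric positive semi-definite matrix with dimnames `species`.
#' @examples
#' bm_covariance(read_newick("((A:1,B:1):1,C:2);"), c("A", "B", "C"))
#' @export
bm_covariance <- function(tree, species = tree$tip.label) {
  validate_phylo(tree)
  bad <- setdiff(species, tree$tip.label)
  if (length(bad)) {
    stop("not leaves of the tree: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  depths <- ape::node.depth.edgelength(tree)
  idx <- match(species, tree$tip.label)
  n <- length(idx)
  mr <- ape::mrca(tree, full = FALSE)
  C <- matrix(0, n, n, dimnames = list(species, species))
  for (i in seq_len(n)) {
    for (j in i:n) {
      a <- if (i == j) idx[i] else mr[idx[i], idx[j]]
      C[i, j] <- C[j, i] <- depths[a]
    }
  }
  C
}

# one GLS fit y ~ X under covariance C via Cholesky whitening
gls_solve <- function(y, X, C) {
  R <- tryCatch(chol(C), error = function(e) {
    stop("Brownian covariance is singular (zero terminal branch?): ",
         conditionMessage(e), call. = FALSE)
  })
  # whiten: solve R' z = y  =>  z = (R')^{-1} y, cov(z) = sigma2 I
  z <- backsolve(R, y, transpose = TRUE)
  W <- backsolve(R, X, transpose = TRUE)
  qrW <- qr(W)
  if (qrW$rank < ncol(W)) {
    stop("design matrix is singular: column '",
         colnames(X)[qrW$rank + 1L] %||% "?", "'", call. = FALSE)
  }
  beta <- qr.coef(qrW, z)
  resid <- z - W %*% beta
  n <- length(y); p <- ncol(X)
  sigma2 <- sum(resid^2) / (n - p)
  XtX_inv <- chol2inv(qr.R(qrW))
  se <- sqrt(sigma2 * diag(XtX_inv))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  logdetC <- 2 * sum(log(diag(R)))
  loglik <- -0.5 * (n * log(2 * pi * sigma2) + logdetC +
                      sum(resid^2) / sigma2)
  list(coefficients = stats::setNames(as.vector(beta), colnames(X)),
       std.error = stats::setNames(se, colnames(X)),
       statistic = stats::setNames(as.vector(tval), colnames(X)),
       p.value = stats::setNames(as.vector(pval), colnames(X)),
       sigma2 = sigma2, df = n - p, n = n, logLik = loglik)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Phylogenetic generalized least squares under Brownian motion
#'
#' Fits `response ~ predictor` by GLS with residual covariance proportional
#' to the Brownian tree covariance. By default each predictor is fitted in
#' its own simple regression (one panel per predictor, the convention for
#' genome-size correlate scans); `multiple = TRUE` fits them jointly
#' instead. Species with missing values in fitted columns are dropped with
#' a warning.
#'
#' @param traits Data frame with a `species` column, the response and the
#'   predictors.
#' @param response Name of the response column (e.g. genome size in Mbp).
#' @param predictors Character vector of predictor column names.
#' @param tree Rooted `phylo`; must contain every fitted species.
#' @param multiple Fit one joint multiple regression instead of
#'   per-predictor simple regressions.
#' @return An object of class `pgls_fit`; see [tidy.pgls_fit()] and
#'   [glance.pgls_fit()].
#' @examples
#' sim <- sim_brownian_traits(sim_species_tree(12, seed = 3)$tree,
#'                            beta = c(1, 0.8), sigma2 = 0.5, seed = 3)
#' fit <- pgls_fit(sim$traits, "y", "x1", sim_species_tree(12, seed = 3)$tree)
#' tidy(fit)
#' @export
pgls_fit <- function(traits, response, predictors, tree, multiple = FALSE) {
  validate_phylo(tree)
  if (!"species" %in% names(traits)) {
    stop("`traits` needs a `species` column", call. = FALSE)
  }
  cols <- c(response, predictors)
  miss_col <- setdiff(cols, names(traits))
  if (length(miss_col)) {
    stop("missing trait columns: ", paste(miss_col, collapse = ", "),
         call. = FALSE)
  }
  bad_sp <- setdiff(traits$species, tree$tip.label)
  if (length(bad_sp)) {
    stop("species not in tree: ", paste(bad_sp, collapse = ", "),
         call. = FALSE)
  }
  keep <- stats::complete.cases(traits[, cols])
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " species with missing trait values: ",
            paste(traits$species[!keep], collapse = ", "), call. = FALSE)
    traits <- traits[keep, ]
  }
  n <- nrow(traits)
  p_max <- if (multiple) length(predictors) + 1L else 2L
  if (n < p_max + 1L) stop("too few species for the requested fit",
                           call. = FALSE)
  C <- bm_covariance(tree, traits$species)
  y <- traits[[response]]
  fits <- if (multiple) {
    X <- cbind(`(Intercept)` = 1,
               as.matrix(traits[, predictors, drop = FALSE]))
    list(joint = gls_solve(y, X, C))
  } else {
    stats::setNames(lapply(predictors, function(pr) {
      X <- cbind(`(Intercept)` = 1, as.matrix(traits[, pr, drop = FALSE]))
      gls_solve(y, X, C)
    }), predictors)
  }
  structure(list(fits = fits, response = response, predictors = predictors,
                 multiple = multiple, n = n, species = traits$species,
                 data = traits, tree = tree),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS (Brownian) fit of", x$response, "on",
      paste(x$predictors, collapse = ", "),
      if (x$multiple) "(joint)" else "(one predictor per fit)",
      "- n =", x$n, "species\n")
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a PGLS fit
#'
#' @param x A `pgls_fit`.
#' @param ... Unused.
#' @return Tibble with one row per coefficient: `fit` (predictor panel),
#'   `term`, `estimate`, `std.error`, `statistic`, `df`, `p.value`.
#' @export
tidy.pgls_fit <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$fits), function(nm) {
    f <- x$fits[[nm]]
    tibble::tibble(fit = nm, term = names(f$coefficients),
                   estimate = unname(f$coefficients),
                   std.error = unname(f$std.error),
                   statistic = unname(f$statistic),
                   df = f$df, p.value = unname(f$p.value))
  }))
}

#' Glance at a PGLS fit
#'
#' @param x A `pgls_fit`.
#' @param ... Unused.
#' @return Tibble with one row per fitted panel: `fit`, `n`, `sigma2`,
#'   `logLik`.
#' @export
glance.pgls_fit <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$fits), function(nm) {
    f <- x$fits[[nm]]
    tibble::tibble(fit = nm, n = f$n, sigma2 = f$sigma2, logLik = f$logLik)
  }))
}

#' Scatter panels of a PGLS fit
#'
#' One panel per predictor with the GLS regression line.
#'
#' @param object A `pgls_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pgls_fit <- function(object, ...) {
  td <- tidy(object)
  long <- tidyr::pivot_longer(
    object$data[, c("species", object$response, object$predictors)],
    cols = dplyr::all_of(object$predictors),
    names_to = "predictor", values_to = "x")
  lines <- td |>
    dplyr::filter(.data$term != "(Intercept)") |>
    dplyr::select(predictor = "fit", slope = "estimate") |>
    dplyr::left_join(
      td |> dplyr::filter(.data$term == "(Intercept)") |>
        dplyr::select(predictor = "fit", intercept = "estimate"),
      by = "predictor")
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data[[object$response]])) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept),
      colour = "steelblue") +
    ggplot2::facet_wrap(~predictor, scales = "free_x") +
    ggplot2::labs(x = NULL, y = object$response,
                  title = "PGLS (Brownian) per-predictor fits")
}
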