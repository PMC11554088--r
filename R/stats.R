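# log point-probability of a contingency table under the fixed-margins
# (multivariate hypergeometric) null:
#   P = prod(R_i!) prod(C_j!) / (N! prod(n_ij!))
.log_table_prob <- function(m) {
  sum(lgamma(rowSums(m) + 1)) + sum(lgamma(colSums(m) + 1)) -
    lgamma(sum(m) + 1) - sum(lgamma(m + 1))
}

#' Fisher's exact test by exhaustive enumeration
#'
#' Two-sided exact test of independence for an r x c table of counts,
#' using the probability-mass definition of "as extreme": the p-value sums
#' the null probabilities of every table with the observed margins whose
#' point probability does not exceed the observed table's (the convention
#' of the common commercial statistics packages). 2 x 2 tables are
#' enumerated directly over the hypergeometric range; larger tables by
#' depth-first enumeration of all tables with the observed margins, guarded
#' by a state budget. Rows and columns that are entirely zero are dropped;
#' a table left with a single row or column carries no association and
#' returns p = 1.
#'
#' @param x Matrix (or table) of non-negative integer counts.
#' @param max_tables Enumeration budget; exceeding it raises an error
#'   advising [fisher_exact_mc()].
#' @return List of class `fisher_result`: `p_value`, `method`
#'   (`"enumeration"`), `n_tables` enumerated.
#' @examples
#' fisher_exact(matrix(c(3, 0, 0, 3), 2))$p_value  # 0.1
#' @export
fisher_exact <- function(x, max_tables = 2e6) {
  m <- .as_count_matrix(x)
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2) {
    return(structure(list(p_value = 1, method = "enumeration", n_tables = 1L),
                     class = "fisher_result"))
  }
  eps <- 1e-7
  obs_lp <- .log_table_prob(m)
  if (nrow(m) == 2 && ncol(m) == 2) {
    R <- rowSums(m); C <- colSums(m); N <- sum(m)
    a <- max(0, C[1] - R[2]):min(R[1], C[1])
    probs <- dhyper(a, R[1], R[2], C[1])
    p <- sum(probs[log(probs) <= obs_lp + eps])
    return(structure(list(p_value = min(p, 1), method = "enumeration",
                          n_tables = length(a)),
                     class = "fisher_result"))
  }
  # depth-first enumeration: fill cells row-major; last column and last row
  # are forced by the margins.
  R <- rowSums(m); C <- colSums(m)
  nr <- nrow(m); nc <- ncol(m)
  env <- new.env(parent = emptyenv())
  env$p <- 0; env$count <- 0L
  cur <- matrix(0, nr, nc)
  recurse <- function(i, j, row_left, col_left) {
    if (i == nr) {
      # last row forced
      if (any(col_left < 0)) return(invisible(NULL))
      cur[nr, ] <<- col_left
      env$count <- env$count + 1L
      if (env$count > max_tables) {
        abort(paste0("enumeration exceeds the ", format(max_tables),
                     "-table budget; use fisher_exact_mc()"),
              class = "edds_budget_error")
      }
      lp <- .log_table_prob(cur)
      if (lp <= obs_lp + eps) env$p <- env$p + exp(lp)
      return(invisible(NULL))
    }
    if (j == nc) {
      if (row_left > col_left[nc]) return(invisible(NULL))
      cur[i, nc] <<- row_left
      col_left[nc] <- col_left[nc] - row_left
      recurse(i + 1L, 1L, R[i + 1L], col_left)
      return(invisible(NULL))
    }
    for (v in 0:min(row_left, col_left[j])) {
      cur[i, j] <<- v
      cl <- col_left; cl[j] <- cl[j] - v
      recurse(i, j + 1L, row_left - v, cl)
    }
    invisible(NULL)
  }
  recurse(1L, 1L, R[1], C)
  structure(list(p_value = min(env$p, 1), method = "enumeration",
                 n_tables = env$count),
            class = "fisher_result")
}

#' Monte-Carlo Fisher exact test
#'
#' Estimates the same probability-mass two-sided p-value as
#' [fisher_exact()] by sampling tables with the observed margins
#' (Patefield's algorithm via [stats::r2dtable()]). Reported with its
#' Monte-Carlo standard error.
#'
#' @param x Matrix of non-negative integer counts.
#' @param n_sim Number of sampled tables (default 1e5).
#' @param seed Optional integer seed for reproducibility.
#' @return List of class `fisher_result`: `p_value`, `mc_se`, `method`
#'   (`"monte_carlo"`), `n_sim`.
#' @export
fisher_exact_mc <- function(x, n_sim = 1e5, seed = NULL) {
  m <- .as_count_matrix(x)
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2) {
    return(structure(list(p_value = 1, mc_se = 0, method = "monte_carlo",
                          n_sim = 0L),
                     class = "fisher_result"))
  }
  if (!is.null(seed)) set.seed(seed)
  obs_lp <- .log_table_prob(m)
  eps <- 1e-7
  sims <- r2dtable(n_sim, rowSums(m), colSums(m))
  hits <- vapply(sims, function(s) .log_table_prob(s) <= obs_lp + eps,
                 logical(1))
  p <- mean(hits)
  structure(list(p_value = p,
                 mc_se = sqrt(p * (1 - p) / n_sim),
                 method = "monte_carlo",
                 n_sim = as.integer(n_sim)),
            class = "fisher_result")
}

.as_count_matrix <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    abort("contingency table must hold non-negative integers",
          class = "edds_schema_error")
  }
  if (sum(m) == 0) {
    abort("contingency table must have at least one positive entry",
          class = "edds_schema_error")
  }
  m
}

#' @export
print.fisher_result <- function(x, ...) {
  cat(sprintf("Fisher exact test (%s): p = %.6g", x$method, x$p_value))
  if (!is.null(x$mc_se)) cat(sprintf(" +/- %.2g (MC se)", x$mc_se))
  cat("\n")
  invisible(x)
}

#' Binomial confidence interval, modified Wald (Agresti-Coull)
#'
#' The modified-Wald interval centres on the adjusted proportion
#' \eqn{\tilde p = (x + z^2/2) / (n + z^2)} with half-width
#' \eqn{z \sqrt{\tilde p (1 - \tilde p) / (n + z^2)}}, clipped to [0, 1];
#' z is the exact two-sided normal quantile for the requested level (1.96
#' at 95%). At the 95% level this is the familiar "add 2 successes and 2
#' failures" interval, the method behind the intervals printed by common
#' statistics packages under the name "Wald". The unadjusted (plain Wald)
#' interval is provided for comparison as [binomial_ci_wald()]; for small
#' x it is markedly narrower and less trustworthy.
#'
#' @param x Number of successes (0 <= x <= n).
#' @param n Number of trials (>= 1).
#' @param level Confidence level in (0, 1), default 0.95.
#' @return List of class `binom_ci`: `successes`, `n`, `level`, `point`
#'   (x/n), `adjusted_point`, `lower`, `upper`, `method`.
#' @examples
#' binomial_ci_modified_wald(1, 49)  # 2% (0%-12%) to whole percents
#' @export
binomial_ci_modified_wald <- function(x, n, level = 0.95) {
  .check_binom(x, n, level)
  z <- qnorm(1 - (1 - level) / 2)
  p_adj <- (x + z^2 / 2) / (n + z^2)
  hw <- z * sqrt(p_adj * (1 - p_adj) / (n + z^2))
  structure(list(successes = as.integer(x), n = as.integer(n), level = level,
                 point = x / n, adjusted_point = p_adj,
                 lower = max(0, p_adj - hw), upper = min(1, p_adj + hw),
                 method = "modified_wald"),
            class = "binom_ci")
}

#' Binomial confidence interval, plain Wald
#'
#' \eqn{\hat p \pm z \sqrt{\hat p (1 - \hat p) / n}}, clipped to [0, 1].
#' Degenerate at x = 0 or x = n (zero width); prefer
#' [binomial_ci_modified_wald()].
#'
#' @inheritParams binomial_ci_modified_wald
#' @return A `binom_ci` with `method = "wald"`.
#' @export
binomial_ci_wald <- function(x, n, level = 0.95) {
  .check_binom(x, n, level)
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  hw <- z * sqrt(p * (1 - p) / n)
  structure(list(successes = as.integer(x), n = as.integer(n), level = level,
                 point = p, adjusted_point = p,
                 lower = max(0, p - hw), upper = min(1, p + hw),
                 method = "wald"),
            class = "binom_ci")
}

.check_binom <- function(x, n, level) {
  if (!(is.numeric(n) && n >= 1 && n == round(n))) {
    abort("n must be a positive integer", class = "edds_schema_error")
  }
  if (!(is.numeric(x) && x >= 0 && x <= n && x == round(x))) {
    abort("x must be an integer in [0, n]", class = "edds_schema_error")
  }
  stopifnot(level > 0, level < 1)
}

#' @export
print.binom_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% [%s %d%% CI: %.1f%% - %.1f%%]\n",
              x$successes, x$n, 100 * x$point, x$method,
              round(100 * x$level), 100 * x$lower, 100 * x$upper))
  invisible(x)
}

#' Rank concordance between two abundance measures
#'
#' Spearman rank correlation between two per-taxon abundance vectors (eDNA
#' copies vs trawl weights, copies vs reads, ...) over the union of taxa,
#' with absences treated as zeros. Requires at least three taxa present in
#' both measures. Also returns the paired per-species table for export or
#' plotting.
#'
#' @param x,y Named numeric vectors, taxon -> value.
#' @return List: `rho` (Spearman), `n_taxa`, `n_common`, `table` (tibble
#'   `taxon`, `x`, `y`).
#' @export
abundance_concordance <- function(x, y) {
  if (is.null(names(x)) || is.null(names(y))) {
    abort("x and y must be named by taxon", class = "edds_schema_error")
  }
  common <- intersect(names(x)[x > 0], names(y)[y > 0])
  if (length(common) < 3) {
    abort("need at least 3 taxa present in both measures",
          class = "edds_schema_error")
  }
  taxa <- sort(union(names(x), names(y)))
  xv <- setNames(rep(0, length(taxa)), taxa); xv[names(x)] <- x
  yv <- setNames(rep(0, length(taxa)), taxa); yv[names(y)] <- y
  list(rho = cor(xv, yv, method = "spearman"),
       n_taxa = length(taxa),
       n_common = length(common),
       table = tibble::tibble(taxon = taxa, x = unname(xv), y = unname(yv)))
}
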