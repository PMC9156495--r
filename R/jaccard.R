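#' Jaccard-Tanimoto coefficient of two binary vectors
#'
#' J = |u AND v| / |u OR v|, the intersection-over-union similarity of two
#' presence lists. By convention an all-zero pair compares equal (J = 1):
#' two scopes where nothing is present are identical.
#'
#' @param u,v Binary vectors (0/1 or logical) of equal length >= 1.
#' @return List with \code{J}, \code{n_intersection}, \code{n_union}.
#' @examples
#' jaccard(c(1, 1, 1, 0), c(0, 1, 1, 1))$J  # 0.5
#' @export
jaccard <- function(u, v) {
  u <- check_binary(u, "u")
  v <- check_binary(v, "v")
  if (length(u) != length(v))
    stop("binary vectors differ in length (", length(u), " vs ", length(v), ")",
         call. = FALSE)
  n11 <- sum(u & v)
  n_union <- sum(u | v)
  list(J = if (n_union == 0L) 1 else n11 / n_union,
       n_intersection = as.integer(n11),
       n_union = as.integer(n_union))
}

check_binary <- function(x, label) {
  if (is.logical(x)) x <- as.integer(x)
  if (length(x) < 1L || anyNA(x) || !all(x %in% c(0L, 1L)))
    stop(label, " must be a binary vector (entries 0/1) of length >= 1",
         call. = FALSE)
  as.integer(x)
}

#' Parameters for the Jaccard-Tanimoto permutation test
#'
#' @param B_permutations Number of permutations (default 10000, minimum 100).
#' @param seed Integer seed; mandatory, every reported p must be reproducible.
#' @param alternative \code{"two_sided"} (default), \code{"less_similar"}
#'   (observed lists more different than chance) or \code{"more_similar"}.
#' @return A \code{jaccard_params} object.
#' @export
jaccard_params <- function(B_permutations = 10000L, seed,
                           alternative = c("two_sided", "less_similar",
                                           "more_similar")) {
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(as.integer(seed))))
    stop("an explicit integer seed is mandatory for permutation tests",
         call. = FALSE)
  B <- as.integer(B_permutations)
  if (is.na(B) || B < 100L)
    stop("B_permutations must be >= 100", call. = FALSE)
  structure(list(B_permutations = B, seed = as.integer(seed),
                 alternative = match.arg(alternative)),
            class = "jaccard_params")
}

#' Jaccard-Tanimoto permutation test
#'
#' Tests the null of no phenotype-linked difference between two presence
#' lists. \code{u} is held fixed and the entries of \code{v} are permuted
#' uniformly at random B times, preserving the margin (number of 1s) of each
#' vector; the observed J is compared to the permutation distribution. Under
#' a uniform random permutation of \code{v} the overlap |u AND v_perm| is
#' hypergeometric, and the null is sampled through that identity, which is
#' exactly equivalent to permuting \code{v} and much faster.
#'
#' The two-sided p-value is
#' \code{(1 + #\{|J_b - mean(J_perm)| >= |J_obs - mean(J_perm)|\}) / (B + 1)};
#' the one-sided variants use the corresponding tail (\code{less_similar}
#' counts \code{J_b <= J_obs}). p is never 0; the minimum is 1/(B+1).
#'
#' Degenerate inputs (either vector all-zero or all-one) carry no
#' permutation information; the result is flagged \code{uninformative} with
#' p = 1 so whole-network runs never abort on sparse scopes.
#'
#' @inheritParams jaccard
#' @param params A \code{\link{jaccard_params}}.
#' @return A \code{jaccard_result}: list with \code{J}, \code{p},
#'   \code{n_intersection}, \code{n_union}, \code{uninformative}, and a
#'   \code{params} echo.
#' @export
jaccard_test <- function(u, v, params) {
  stopifnot(inherits(params, "jaccard_params"))
  u <- check_binary(u, "u")
  v <- check_binary(v, "v")
  obs <- jaccard(u, v)
  n <- length(u)
  ku <- sum(u)
  kv <- sum(v)
  degenerate <- ku %in% c(0L, n) || kv %in% c(0L, n)
  if (degenerate) {
    return(structure(list(J = obs$J, p = 1,
                          n_intersection = obs$n_intersection,
                          n_union = obs$n_union,
                          uninformative = TRUE, params = params),
                     class = "jaccard_result"))
  }
  B <- params$B_permutations
  J_perm <- with_seed(params$seed, {
    n11_b <- rhyper(B, m = ku, n = n - ku, k = kv)
    n11_b / (ku + kv - n11_b)
  })
  eps <- 1e-12
  p <- switch(params$alternative,
    two_sided = {
      mu <- mean(J_perm)
      (1 + sum(abs(J_perm - mu) >= abs(obs$J - mu) - eps)) / (B + 1)
    },
    less_similar = (1 + sum(J_perm <= obs$J + eps)) / (B + 1),
    more_similar = (1 + sum(J_perm >= obs$J - eps)) / (B + 1)
  )
  structure(list(J = obs$J, p = p,
                 n_intersection = obs$n_intersection,
                 n_union = obs$n_union,
                 uninformative = FALSE, params = params),
            class = "jaccard_result")
}

#' @export
print.jaccard_result <- function(x, ...) {
  cat(sprintf("<jaccard_result> J = %.4f (|intersection| = %d, |union| = %d), p = %.4g%s\n",
              x$J, x$n_intersection, x$n_union, x$p,
              if (x$uninformative) " [uninformative: degenerate margin]" else ""))
  invisible(x)
}

# Evaluate an expression under a temporary RNG state; the caller's
# .Random.seed is restored afterwards so library code never perturbs the
# user's random stream.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}
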