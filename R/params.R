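# Promoter parameterisation and transition-matrix construction for the
# five-microstate chain over {f, T, M, S, D}:
#   f = free promoter, T = TBP:TBS (monomeric TBP on its binding site),
#   M = TBS:TBP:Mot1p, S = TBS:TBP:SAGA, D = TBS:TBP:TFIID.
# S and D are the transcribing ("On") macrostate; f, T, M are "Off".

#' Microstate labels of the promoter chain
#'
#' Returns the five microstate labels in their canonical order: free
#' promoter (`f`), monomeric TBP bound to its site (`T`), the Mot1p-engaged
#' complex (`M`), the SAGA co-activator assembly (`S`) and the TFIID
#' holo-complex (`D`). `S` and `D` are the transcriptionally active ("On")
#' states; `f`, `T` and `M` are silent ("Off").
#'
#' @return A character vector of length five.
#' @export
#' @examples
#' microstates()
microstates <- function() c("f", "T", "M", "S", "D")

# Integer codes of the On states within microstates()
ON_STATES <- c(4L, 5L)

check_scalar <- function(x, nm, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", nm))
  }
  if (x < lo || x > hi) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", nm,
                  format(lo), format(hi), format(x)))
  }
  invisible(x)
}

#' Promoter archetype parameters
#'
#' Bundles the tunable quantities of the promoter-state chain: the per-step
#' probability that the free promoter binds monomeric TBP (`affinity`, the
#' f->T edge), the per-step probability of direct TFIID holo-complex
#' assembly (`tfiid_recruit`, f->D), the probability that DNA-bound
#' monomeric TBP is engaged by a partner (`engage`), the probability that
#' the engaging partner is the Mot1p remodeller rather than SAGA
#' (`competition`), the spontaneous TBP:TBS dissociation probability
#' (`t_off`, T->f), mean residence times in steps of the Mot1p-, SAGA- and
#' TFIID-bound assemblies (`r_M`, `r_S`, `r_D`; geometric dwell with exit
#' probability 1/r), and expression units accrued per step spent in the
#' SAGA (`b_S`) and TFIID (`b_D`) On states.
#'
#' Constraints enforced: all probabilities lie in \[0, 1\],
#' `affinity + tfiid_recruit <= 1`, `engage + t_off <= 1`, residences are
#' `>= 1` and bursts are `>= 0`.
#'
#' @param affinity Probability per step that the free promoter binds
#'   monomeric TBP (f->T).
#' @param tfiid_recruit Probability per step of direct TFIID assembly on
#'   the free promoter (f->D).
#' @param engage Probability per step that DNA-bound monomeric TBP is
#'   engaged by a partner (Mot1p or SAGA).
#' @param competition Probability that the engaging partner is Mot1p rather
#'   than SAGA.
#' @param t_off Spontaneous TBP:TBS dissociation probability per step
#'   (T->f).
#' @param r_M,r_S,r_D Mean residence times (steps, >= 1) of the M, S and D
#'   states.
#' @param b_S,b_D Expression units added per step spent in S and D.
#' @param label Optional archetype label carried through results.
#' @return An object of class `promoter_params`.
#' @seealso [params_tata_box()], [params_tata_like()],
#'   [build_transition_matrix()]
#' @export
#' @examples
#' promoter_params(affinity = 0.5, competition = 0.9)
promoter_params <- function(affinity = 0.5, tfiid_recruit = 0.05,
                            engage = 0.8, competition = 0.9, t_off = 0.05,
                            r_M = 2, r_S = 10, r_D = 50,
                            b_S = 5, b_D = 1, label = "promoter") {
  check_scalar(affinity, "affinity", 0, 1)
  check_scalar(tfiid_recruit, "tfiid_recruit", 0, 1)
  check_scalar(engage, "engage", 0, 1)
  check_scalar(competition, "competition", 0, 1)
  check_scalar(t_off, "t_off", 0, 1)
  if (affinity + tfiid_recruit > 1 + 1e-12) {
    abort("`affinity` + `tfiid_recruit` must not exceed 1.")
  }
  if (engage + t_off > 1 + 1e-12) {
    abort("`engage` + `t_off` must not exceed 1.")
  }
  check_scalar(r_M, "r_M", 1, Inf)
  check_scalar(r_S, "r_S", 1, Inf)
  check_scalar(r_D, "r_D", 1, Inf)
  check_scalar(b_S, "b_S", 0, Inf)
  check_scalar(b_D, "b_D", 0, Inf)
  structure(
    list(affinity = affinity, tfiid_recruit = tfiid_recruit,
         engage = engage, competition = competition, t_off = t_off,
         r_M = r_M, r_S = r_S, r_D = r_D, b_S = b_S, b_D = b_D,
         label = label),
    class = "promoter_params"
  )
}

as_promoter_params <- function(x) {
  if (inherits(x, "promoter_params")) return(x)
  if (is.list(x)) return(do.call(promoter_params, x))
  abort("`params` must be a `promoter_params` object (see `promoter_params()`).")
}

#' Modify promoter parameters
#'
#' Returns a copy of `params` with the named fields replaced, re-running
#' all validity checks.
#'
#' @param params A [promoter_params()] object.
#' @param ... Named fields to override.
#' @return A `promoter_params` object.
#' @export
update_params <- function(params, ...) {
  params <- as_promoter_params(params)
  do.call(promoter_params, modifyList(unclass(params), list(...)))
}

#' @export
print.promoter_params <- function(x, ...) {
  cat(sprintf("<promoter_params: %s>\n", x$label))
  cat(sprintf("  affinity (f->T) %.3g | tfiid_recruit (f->D) %.3g | t_off %.3g\n",
              x$affinity, x$tfiid_recruit, x$t_off))
  cat(sprintf("  engage %.3g | competition (Mot1p vs SAGA) %.3g\n",
              x$engage, x$competition))
  cat(sprintf("  residence M/S/D: %.3g/%.3g/%.3g steps | burst S/D: %.3g/%.3g\n",
              x$r_M, x$r_S, x$r_D, x$b_S, x$b_D))
  invisible(x)
}

#' TATA-box promoter archetype
#'
#' High monomeric-TBP affinity with Mot1p-dominant competition: monomeric
#' TBP binds readily, Mot1p usually outcompetes SAGA and evicts it quickly
#' (short Mot1p residence), SAGA has intermediate and TFIID long residence,
#' and the SAGA burst is five-fold larger than the TFIID per-step output.
#'
#' @param ... Field overrides passed to [promoter_params()].
#' @return A `promoter_params` object.
#' @export
params_tata_box <- function(...) {
  base <- list(affinity = 0.5, tfiid_recruit = 0.05, engage = 0.8,
               competition = 0.9, t_off = 0.05, r_M = 2, r_S = 10,
               r_D = 50, b_S = 5, b_D = 1, label = "TATA-box")
  do.call(promoter_params, modifyList(base, list(...)))
}

#' TATA-like promoter archetype
#'
#' Near-zero monomeric-TBP affinity: TBP arrives essentially only as part
#' of the TFIID holo-complex, which has a long residence time, giving a
#' stable transcriptional output. Other fields match the TATA-box
#' archetype so the two differ only in their TBP delivery route.
#'
#' @param ... Field overrides passed to [promoter_params()].
#' @return A `promoter_params` object.
#' @export
params_tata_like <- function(...) {
  base <- list(affinity = 0.02, tfiid_recruit = 0.2, engage = 0.8,
               competition = 0.9, t_off = 0.05, r_M = 2, r_S = 10,
               r_D = 50, b_S = 5, b_D = 1, label = "TATA-like")
  do.call(promoter_params, modifyList(base, list(...)))
}

#' Build the promoter-state transition matrix
#'
#' Constructs the 5x5 row-stochastic transition matrix over the microstates
#' `f, T, M, S, D`. The topology encodes the assembly decision tree: the
#' free promoter binds monomeric TBP (f->T, `affinity`) or assembles TFIID
#' directly (f->D, `tfiid_recruit`); DNA-bound monomeric TBP either falls
#' off (T->f, `t_off`) or is engaged by Mot1p (T->M, `engage *
#' competition`) or SAGA (T->S, `engage * (1 - competition)`); each bound
#' complex dissociates back to the free promoter with per-step probability
#' `1/r` (geometric residence). All other transitions are zero; in
#' particular TFIID never completes around pre-bound monomeric TBP
#' (T->D = 0) and residual probability mass stays on the diagonal.
#'
#' @param params A [promoter_params()] object (or a list coercible to one).
#' @return A 5x5 numeric matrix with `microstates()` dimnames; rows sum to
#'   one exactly.
#' @export
#' @examples
#' build_transition_matrix(params_tata_box())
build_transition_matrix <- function(params) {
  p <- as_promoter_params(params)
  states <- microstates()
  P <- matrix(0, 5, 5, dimnames = list(states, states))
  P["f", ] <- c(1 - p$affinity - p$tfiid_recruit, p$affinity, 0, 0,
                p$tfiid_recruit)
  P["T", ] <- c(p$t_off, 1 - p$t_off - p$engage,
                p$engage * p$competition, p$engage * (1 - p$competition), 0)
  P["M", ] <- c(1 / p$r_M, 0, 1 - 1 / p$r_M, 0, 0)
  P["S", ] <- c(1 / p$r_S, 0, 0, 1 - 1 / p$r_S, 0)
  P["D", ] <- c(1 / p$r_D, 0, 0, 0, 1 - 1 / p$r_D)
  # tidy tiny float residue so rows sum to 1 exactly
  diag(P) <- diag(P) + (1 - rowSums(P))
  P
}

check_stochastic <- function(P, arg = "P") {
  if (!is.matrix(P) || nrow(P) != ncol(P) || !is.numeric(P)) {
    abort(sprintf("`%s` must be a square numeric matrix.", arg))
  }
  if (any(P < -1e-12) || any(abs(rowSums(P) - 1) > 1e-9)) {
    abort(sprintf(
      "`%s` must be row-stochastic (entries >= 0, rows summing to 1).", arg))
  }
  invisible(P)
}

#' Stationary distribution by power iteration
#'
#' Computes the left fixed vector of a row-stochastic matrix by repeated
#' multiplication. Iteration runs on the lazy chain `(I + P) / 2`, which
#' shares the stationary distribution of `P` but is aperiodic, so the
#' iteration converges for any irreducible `P`. Uniqueness is probed by
#' restarting from two extreme corners of the simplex; if the restarts
#' disagree the chain is flagged as reducible and the uniform-start result
#' is returned with a warning.
#'
#' @param P A row-stochastic matrix.
#' @param tol Convergence tolerance on the max absolute update.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return A named probability vector (entries >= 0, summing to 1).
#' @export
#' @examples
#' stationary_distribution(build_transition_matrix(params_tata_box()))
stationary_distribution <- function(P, tol = 1e-12, max_iter = 1e5) {
  check_stochastic(P)
  k <- nrow(P)
  lazy <- (diag(k) + P) / 2
  iterate <- function(v0) {
    v <- v0
    for (i in seq_len(max_iter)) {
      v2 <- as.vector(v %*% lazy)
      if (max(abs(v2 - v)) < tol) return(v2 / sum(v2))
      v <- v2
    }
    abort(sprintf(
      "power iteration did not converge within %d iterations (tol %g).",
      as.integer(max_iter), tol))
  }
  pi_hat <- iterate(rep(1 / k, k))
  alt1 <- iterate(c(1, rep(0, k - 1)))
  alt2 <- iterate(c(rep(0, k - 1), 1))
  if (max(abs(alt1 - pi_hat)) > 1e-6 || max(abs(alt2 - pi_hat)) > 1e-6) {
    warn("chain appears reducible: stationary distribution is not unique; returning the uniform-start fixed vector.")
  }
  stats::setNames(pi_hat, rownames(P))
}

#' Asymptotic standard errors of long-run state frequencies
#'
#' For an ergodic chain, the occupancy fraction of state *i* over `n_steps`
#' steps obeys a central limit theorem with asymptotic variance
#' `pi_i * (2 * Z_ii - 1 - pi_i)`, where `Z = (I - P + 1 pi')^{-1}` is the
#' fundamental matrix. This is the correct standard error for comparing an
#' empirical trajectory's state frequencies with the stationary
#' distribution: the naive binomial error ignores autocorrelation along the
#' chain.
#'
#' @param P A row-stochastic matrix.
#' @param n_steps Trajectory length the frequencies were estimated from.
#' @param pi Optional stationary distribution (computed if missing).
#' @return A named vector of standard errors, one per state.
#' @export
stationary_se <- function(P, n_steps, pi = NULL) {
  check_stochastic(P)
  check_scalar(n_steps, "n_steps", 1, Inf)
  if (is.null(pi)) pi <- stationary_distribution(P)
  k <- nrow(P)
  Z <- solve(diag(k) - P + matrix(pi, k, k, byrow = TRUE))
  sigma2 <- pmax(pi * (2 * diag(Z) - 1 - pi), 0)
  stats::setNames(sqrt(sigma2 / n_steps), rownames(P))
}
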