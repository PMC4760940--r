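## Genotypes: the three differentiation strategies, the threshold decision
## rule, mutation, and strategy classification.

.KINDS <- c(pure = 0L, probabilistic = 1L, decision = 2L)

#' Construct a genotype
#'
#' A genotype carries a differentiation strategy and its evolvable
#' parameters. Three kinds exist:
#' \describe{
#'   \item{pure}{a fixed binary `allele` (1 = sticky). Phenotype equals the
#'     allele; cells switch only through mutation at division.}
#'   \item{probabilistic}{every differentiation event makes the cell sticky
#'     with probability `P`, non-sticky with `1 - P`, independent of its
#'     current state. `P` is clamped to `[0, 1]`.}
#'   \item{decision}{a threshold rule on two sensed cues: the niche
#'     `N` (0 = liquid, 1 = surface) and the sticky fraction `S`. The cell
#'     becomes sticky iff `W1*N + W2*S > theta` (strict, so the all-zero
#'     start genotype never differentiates), else non-sticky
#'     (de-differentiation is allowed).}
#' }
#'
#' `sticky_death` optionally overrides the death probability of *sticky*
#' cells of this genotype (used by the death-rate competition assay);
#' non-sticky cells always die at the configured `P_d`.
#'
#' @param kind `"pure"`, `"probabilistic"` or `"decision"`.
#' @param allele 0 or 1 (pure kind only).
#' @param P differentiation probability in `[0, 1]` (probabilistic kind).
#' @param W1 niche connection weight (decision kind).
#' @param W2 stickiness connection weight (decision kind).
#' @param theta activation threshold (decision kind).
#' @param sticky_death optional death probability override for sticky cells.
#' @param id opaque identifier for lineage tracking.
#' @return An object of class `genotype`.
#' @examples
#' genotype_decision(W1 = 1, W2 = -6, theta = 0.5)
#' @export
genotype <- function(kind = c("pure", "probabilistic", "decision"),
                     allele = 0, P = 0, W1 = 0, W2 = 0, theta = 0,
                     sticky_death = NULL, id = NA_real_) {
  kind <- match.arg(kind)
  if (!allele %in% c(0, 1)) stop("'allele' must be 0 or 1")
  P <- min(max(as.numeric(P), 0), 1)
  if (!is.null(sticky_death)) {
    sticky_death <- as.numeric(sticky_death)
    if (is.na(sticky_death) || sticky_death < 0 || sticky_death > 1)
      stop("'sticky_death' must be a probability")
  }
  structure(list(kind = kind, allele = as.numeric(allele), P = P,
                 W1 = as.numeric(W1), W2 = as.numeric(W2),
                 theta = as.numeric(theta), sticky_death = sticky_death,
                 id = id),
            class = "genotype")
}

#' @rdname genotype
#' @param sticky logical; start allele of a pure genotype.
#' @export
genotype_pure <- function(sticky = FALSE, sticky_death = NULL) {
  genotype("pure", allele = as.numeric(sticky), sticky_death = sticky_death)
}

#' @rdname genotype
#' @export
genotype_probabilistic <- function(P = 0, sticky_death = NULL) {
  genotype("probabilistic", P = P, sticky_death = sticky_death)
}

#' @rdname genotype
#' @export
genotype_decision <- function(W1 = 0, W2 = 0, theta = 0,
                              sticky_death = NULL) {
  genotype("decision", W1 = W1, W2 = W2, theta = theta,
           sticky_death = sticky_death)
}

#' @export
print.genotype <- function(x, ...) {
  par <- switch(x$kind,
    pure = sprintf("allele = %g", x$allele),
    probabilistic = sprintf("P = %g", x$P),
    decision = sprintf("W1 = %g, W2 = %g, theta = %g", x$W1, x$W2, x$theta))
  ov <- if (is.null(x$sticky_death)) ""
        else sprintf(", sticky death = %g", x$sticky_death)
  cat(sprintf("<genotype> %s (%s%s)\n", x$kind, par, ov))
  invisible(x)
}

#' Differentiation decision of a single cell
#'
#' Applies one differentiation event to a cell of genotype `g` given the
#' environmental signal: the niche cue `N` (0 in the liquid, 1 on the
#' surface) and the sensed sticky fraction `S` (fraction of sticky
#' neighbours on the surface; population sticky fraction in the liquid).
#' Pure genotypes never switch (the event is a no-op); probabilistic
#' genotypes draw sticky with probability `P` using R's RNG; decision
#' genotypes apply the deterministic threshold rule `W1*N + W2*S > theta`.
#'
#' @param g a [genotype()].
#' @param N niche cue, 0 or 1.
#' @param S sticky fraction in `[0, 1]`.
#' @param current current phenotype, `"sticky"` or `"non_sticky"`.
#' @return the new phenotype, `"sticky"` or `"non_sticky"`.
#' @export
decide_phenotype <- function(g, N, S, current = "non_sticky") {
  stopifnot(inherits(g, "genotype"))
  current <- match.arg(current, c("non_sticky", "sticky"))
  if (!N %in% c(0, 1)) stop("'N' must be 0 or 1")
  if (is.na(S) || S < 0 || S > 1) stop("'S' must be in [0, 1]")
  switch(g$kind,
    pure = current,
    probabilistic = if (runif(1) < g$P) "sticky" else "non_sticky",
    decision = if (g$W1 * N + g$W2 * S > g$theta) "sticky" else "non_sticky")
}

#' Mutate a genotype at cell division
#'
#' Each evolvable variable mutates independently with probability `mu_r`.
#' Continuous variables (`P`; `W1`, `W2`, `theta`) receive an additive
#' Gaussian perturbation with mean 0 and standard deviation `mu_s`; the pure
#' allele flips; `P` is re-clamped to `[0, 1]` after mutation. The parent is
#' unmodified; a mutated daughter receives a fresh `id` (here `NA`, assigned
#' by the engine during runs). Uses R's RNG.
#'
#' @param g a [genotype()].
#' @param mu_r per-variable mutation probability.
#' @param mu_s mutation step standard deviation.
#' @return a [genotype()].
#' @export
mutate_genotype <- function(g, mu_r = 0.01, mu_s = 0.1) {
  stopifnot(inherits(g, "genotype"))
  out <- g
  mutated <- FALSE
  if (g$kind == "pure") {
    if (runif(1) < mu_r) { out$allele <- 1 - g$allele; mutated <- TRUE }
  } else if (g$kind == "probabilistic") {
    if (runif(1) < mu_r) {
      out$P <- min(max(g$P + rnorm(1, 0, mu_s), 0), 1)
      mutated <- TRUE
    }
  } else {
    for (v in c("W1", "W2", "theta")) {
      if (runif(1) < mu_r) {
        out[[v]] <- g[[v]] + rnorm(1, 0, mu_s)
        mutated <- TRUE
      }
    }
  }
  if (mutated) out$id <- NA_real_
  out
}

## ---- strategy classification -------------------------------------------

.rule_from_decisions <- function(d) {
  # d: logical vector of decisions at S = 0/nn, 1/nn, ..., nn/nn
  n <- length(d)
  if (all(d)) return(list(rule = "always", inverted = FALSE))
  if (!any(d)) return(list(rule = "never", inverted = FALSE))
  k <- sum(d) # candidate: differentiate iff fewer than k sticky neighbours
  if (all(d == c(rep(TRUE, k), rep(FALSE, n - k))))
    return(list(rule = paste0("threshold_", k), inverted = FALSE))
  # non-monotone (possible when W2 > 0): report the count of sticky-S
  # decisions but flag it
  list(rule = paste0("threshold_", k), inverted = TRUE)
}

#' Classify a decision-making genotype
#'
#' Evaluates the threshold rule deterministically on the surface (`N = 1`)
#' at `S = 0, 1/n, ..., n/n` for neighbourhood size `n`, and in the liquid
#' (`N = 0`) over the same `S` grid. The surface rule is `"always"`,
#' `"never"`, or `"threshold_k"`, meaning *differentiate iff fewer than `k`
#' sticky neighbours*; the liquid rule reads *differentiate iff the
#' population sticky fraction is below `k/n`*. Genotypes whose decisions are
#' not monotone decreasing in `S` (possible when `W2 > 0`) are flagged
#' `inverted` rather than silently binned.
#'
#' @param g a [genotype()] of kind `"decision"`.
#' @param spec a [lattice_spec()]; sets the neighbourhood size `n`.
#' @return an object of class `strategy_label`: a list with elements
#'   `surface_rule`, `liquid_rule`, `surface_inverted`, `liquid_inverted`.
#' @examples
#' classify_strategy(climax_genotype(), lattice_spec(5, 5))
#' @export
classify_strategy <- function(g, spec = lattice_spec()) {
  stopifnot(inherits(g, "genotype"))
  if (g$kind != "decision")
    stop("classify_strategy() supports only decision-making genotypes")
  stopifnot(inherits(spec, "lattice_spec"))
  nn <- neighbourhood_size(spec)
  S <- (0:nn) / nn
  surf <- g$W1 * 1 + g$W2 * S > g$theta
  liq <- g$W1 * 0 + g$W2 * S > g$theta
  rs <- .rule_from_decisions(surf)
  rl <- .rule_from_decisions(liq)
  structure(list(surface_rule = rs$rule, liquid_rule = rl$rule,
                 surface_inverted = rs$inverted,
                 liquid_inverted = rl$inverted),
            class = "strategy_label")
}

#' @export
print.strategy_label <- function(x, ...) {
  inv <- function(f) if (f) " [inverted]" else ""
  cat(sprintf("<strategy_label> surface: %s%s; liquid: %s%s\n",
              x$surface_rule, inv(x$surface_inverted),
              x$liquid_rule, inv(x$liquid_inverted)))
  invisible(x)
}

## ---- fixture genotypes --------------------------------------------------

#' Fixture genotypes for the competition assays and life-cycle checks
#'
#' Hand-specified decision-making genotypes realizing the strategies that
#' evolution produces, so the assays are deterministic in strategy space:
#' \describe{
#'   \item{`climax_genotype()`}{surface rule `threshold_1` (differentiate
#'     only with zero sticky neighbours, producing isolated sticky islands),
#'     never sticky in the liquid. `W1 = 1, W2 = -6, theta = 0.5`.}
#'   \item{`colonizer_genotype()`}{surface rule `threshold_2` (filaments of
#'     concatenated sticky cells), never sticky in the liquid.
#'     `W1 = 2, W2 = -6, theta = 0.5`.}
#'   \item{`life_cycle_genotypes()`}{a named list of four genotypes whose
#'     census classifications map to the four life cycles: filamentous
#'     colonies with sticky propagules (`lc1`), sticky islands with sticky
#'     propagules (`lc2`), sticky islands with non-sticky "parasitic"
#'     propagules (`lc3`, the climax genotype), and the unicellular
#'     transient-attachment cycle that is sticky in the liquid and
#'     de-differentiates on the surface (`lc4`).}
#' }
#'
#' @param sticky_death optional sticky-cell death override passed through.
#' @return a [genotype()], or a named list of them.
#' @export
climax_genotype <- function(sticky_death = NULL) {
  genotype_decision(W1 = 1, W2 = -6, theta = 0.5, sticky_death = sticky_death)
}

#' @rdname climax_genotype
#' @export
colonizer_genotype <- function(sticky_death = NULL) {
  genotype_decision(W1 = 2, W2 = -6, theta = 0.5, sticky_death = sticky_death)
}

#' @rdname climax_genotype
#' @export
life_cycle_genotypes <- function() {
  list(
    lc1 = genotype_decision(W1 = -5, W2 = -6, theta = -6.5),
    lc2 = genotype_decision(W1 = -6, W2 = -6, theta = -6.5),
    lc3 = climax_genotype(),
    lc4 = genotype_decision(W1 = -10, W2 = 0, theta = -0.5))
}
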