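## Summary statistics, spatial pattern analysis, strategy census and
## life-cycle classification.

#' Summarize a world state
#'
#' Population sizes and sticky fractions per niche. The surface sticky
#' fraction is reported as `NA` when at most `censor_surface` cells are
#' attached (the censoring rule used for surface statistics: "more than 100
#' cells" is strict, so exactly 100 cells is still censored).
#'
#' @param world a [world_new()] object.
#' @param censor_surface censoring threshold for the surface fraction.
#' @return a one-row data frame: `t`, `n_liquid`, `n_surface`,
#'   `frac_sticky_liquid`, `frac_sticky_surface`, `n_genotypes`.
#' @export
summarize <- function(world, censor_surface = 100L) {
  stopifnot(inherits(world, "sim_world"))
  st <- world_state(world)
  data.frame(
    t = st$t,
    n_liquid = st$n_liquid,
    n_surface = st$n_surface,
    frac_sticky_liquid =
      if (st$n_liquid > 0) st$sticky_liquid / st$n_liquid else 0,
    frac_sticky_surface =
      if (st$n_surface > censor_surface)
        st$sticky_surface / st$n_surface else NA_real_,
    n_genotypes = st$n_genotypes)
}

#' Connected components of sticky surface cells
#'
#' Labels the sticky cells of a surface snapshot by connected component
#' under the lattice adjacency and classifies the overall spatial pattern:
#' \describe{
#'   \item{none}{no sticky cells;}
#'   \item{uniform_sticky}{sticky cells cover more than `uniform_frac` of
#'     the whole lattice (no pattern left to speak of);}
#'   \item{islands}{at least `island_frac` of the components are isolated
#'     single sticky cells;}
#'   \item{filaments}{the modal component size is in `filament_range`
#'     (short concatenations of sticky cells);}
#'   \item{clumps}{some component exceeds the filament range.}
#' }
#' The numeric thresholds operationalize the verbal pattern descriptions
#' and are exposed as arguments.
#'
#' @param grid a surface table as from [world_grid()] (columns `row`,
#'   `col`, `phenotype` or `sticky`).
#' @param spec the [lattice_spec()] the grid lives on.
#' @param island_frac minimum fraction of singleton components for
#'   `islands`.
#' @param filament_range inclusive size range for `filaments`.
#' @param uniform_frac lattice coverage by sticky cells above which the
#'   pattern is `uniform_sticky`.
#' @return an object of class `pattern_report`: list with
#'   `component_sizes` (integer multiset, decreasing) and `pattern_class`.
#' @export
sticky_components <- function(grid, spec, island_frac = 0.9,
                              filament_range = c(2L, 8L),
                              uniform_frac = 0.95) {
  stopifnot(inherits(spec, "lattice_spec"))
  sticky <- if ("sticky" %in% names(grid)) grid$sticky == 1L
            else grid$phenotype == "sticky"
  n_sites <- spec$width * spec$height
  srow <- grid$row[sticky]; scol <- grid$col[sticky]
  ns <- length(srow)
  if (ns == 0L) {
    return(structure(list(component_sizes = integer(0),
                          pattern_class = "none"),
                     class = "pattern_report"))
  }
  # flood fill over an indicator lattice
  key <- (srow - 1L) * spec$width + scol   # 1-based linear index
  idx <- integer(spec$width * spec$height) # 0 = not sticky, else sticky id
  idx[key] <- seq_len(ns)
  comp <- integer(ns)
  ncomp <- 0L
  for (i in seq_len(ns)) {
    if (comp[i] != 0L) next
    ncomp <- ncomp + 1L
    queue <- i
    comp[i] <- ncomp
    while (length(queue) > 0L) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      nb <- neighbours(spec, srow[cur], scol[cur])
      nkey <- (nb[, "row"] - 1L) * spec$width + nb[, "col"]
      for (j in idx[nkey]) {
        if (j != 0L && comp[j] == 0L) {
          comp[j] <- ncomp
          queue <- c(queue, j)
        }
      }
    }
  }
  sizes <- sort(tabulate(comp, nbins = ncomp), decreasing = TRUE)
  cls <- if (ns / n_sites > uniform_frac) {
    "uniform_sticky"
  } else if (mean(sizes == 1L) >= island_frac) {
    "islands"
  } else {
    modal <- as.integer(names(which.max(table(sizes))))
    if (modal >= filament_range[1L] && modal <= filament_range[2L])
      "filaments"
    else if (max(sizes) > filament_range[2L]) "clumps"
    else "islands"
  }
  structure(list(component_sizes = sizes, pattern_class = cls),
            class = "pattern_report")
}

#' @export
print.pattern_report <- function(x, ...) {
  cat(sprintf("<pattern_report> %s: %d components, sizes ",
              x$pattern_class, length(x$component_sizes)))
  cat(paste(head(x$component_sizes, 10L), collapse = " "))
  if (length(x$component_sizes) > 10L) cat(" ...")
  cat("\n")
  invisible(x)
}

#' Strategy census of the most abundant genotypes
#'
#' Sorts a genotype table by abundance (ties broken by genotype id, oldest
#' first) and classifies the `top` most abundant decision-making genotypes
#' in both niches via [classify_strategy()].
#'
#' @param genotypes a genotype table as from [world_genotypes()] or
#'   `sim$genotypes` (columns `id`, `kind`, `W1`, `W2`, `theta`,
#'   `abundance`).
#' @param spec a [lattice_spec()].
#' @param top number of genotypes to classify (25 by default).
#' @return an object of class `strategy_census`: a data frame with columns
#'   `id`, `abundance`, `surface_rule`, `liquid_rule`, `surface_inverted`,
#'   `liquid_inverted`, in abundance order; attribute `truncated` is `TRUE`
#'   when fewer than `top` genotypes were available.
#' @export
strategy_census <- function(genotypes, spec = lattice_spec(), top = 25L) {
  stopifnot(is.data.frame(genotypes))
  g <- genotypes[genotypes$kind == "decision" & genotypes$abundance > 0, ,
                 drop = FALSE]
  g <- g[order(-g$abundance, g$id), , drop = FALSE]
  truncated <- nrow(g) < top
  g <- head(g, top)
  labs <- lapply(seq_len(nrow(g)), function(i) {
    classify_strategy(genotype_decision(g$W1[i], g$W2[i], g$theta[i]), spec)
  })
  out <- data.frame(
    id = g$id,
    abundance = g$abundance,
    surface_rule = vapply(labs, `[[`, "", "surface_rule"),
    liquid_rule = vapply(labs, `[[`, "", "liquid_rule"),
    surface_inverted = vapply(labs, `[[`, NA, "surface_inverted"),
    liquid_inverted = vapply(labs, `[[`, NA, "liquid_inverted"))
  attr(out, "truncated") <- truncated
  class(out) <- c("strategy_census", "data.frame")
  out
}

.rule_threshold <- function(rule) {
  ifelse(grepl("^threshold_", rule),
         as.integer(sub("^threshold_", "", rule)), NA_integer_)
}

# A liquid rule "produces sticky propagules" when the genotype
# differentiates in the liquid at least at low population stickiness:
# "always" or any threshold rule.
.liquid_sticky_propagules <- function(rule) {
  rule == "always" | grepl("^threshold_", rule)
}

#' Classify the evolved life cycle
#'
#' Decision table over the dominant (most abundant) strategy of a census
#' and the end-state surface pattern:
#' \describe{
#'   \item{LC1_filament_fission}{surface rule `threshold_k` with
#'     `k >= 2` (filamentous colonies) and sticky propagules in the
#'     liquid;}
#'   \item{LC2_island_fission}{surface `threshold_1` (isolated sticky
#'     islands) and sticky propagules;}
#'   \item{LC3_parasitic_propagules}{surface `threshold_1` and liquid rule
#'     `never` — propagules stay non-sticky and colonize by exploiting
#'     resident sticky cells;}
#'   \item{LC4_unicellular_transient}{surface `never` and liquid `always` —
#'     cells become sticky in the liquid, attach, then de-differentiate.}
#' }
#' Combinations matching none of the rows are returned as `unclassified`,
#' never silently binned.
#'
#' @param census a [strategy_census()].
#' @param pattern optionally, the matching [sticky_components()] report
#'   (recorded alongside the label).
#' @return an object of class `life_cycle_label`: list with `label`,
#'   `dominant` (the dominant rules), and `pattern_class`.
#' @export
classify_life_cycle <- function(census, pattern = NULL) {
  stopifnot(inherits(census, "strategy_census"))
  if (nrow(census) == 0L)
    return(structure(list(label = "unclassified", dominant = NULL,
                          pattern_class = pattern$pattern_class),
                     class = "life_cycle_label"))
  sr <- census$surface_rule[1L]
  lr <- census$liquid_rule[1L]
  k <- .rule_threshold(sr)
  lab <- if (!is.na(k) && k >= 2L && .liquid_sticky_propagules(lr)) {
    "LC1_filament_fission"
  } else if (!is.na(k) && k == 1L && .liquid_sticky_propagules(lr)) {
    "LC2_island_fission"
  } else if (!is.na(k) && k == 1L && lr == "never") {
    "LC3_parasitic_propagules"
  } else if (sr == "never" && lr == "always") {
    "LC4_unicellular_transient"
  } else {
    "unclassified"
  }
  structure(list(label = lab,
                 dominant = c(surface = sr, liquid = lr),
                 pattern_class = pattern$pattern_class),
            class = "life_cycle_label")
}

#' @export
print.life_cycle_label <- function(x, ...) {
  cat(sprintf("<life_cycle_label> %s (surface: %s, liquid: %s)\n", x$label,
              x$dominant[["surface"]], x$dominant[["liquid"]]))
  invisible(x)
}
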