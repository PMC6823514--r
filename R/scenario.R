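#' X-linkage retention scenarios
#'
#' A `lineage_scenario` states, for each focal lineage, the male mutation
#' bias `alpha` it experienced while its sequences were X-linked and the
#' retention time `retention_T` (Myr) during which they were X-linked,
#' counted forward from the origin of the sex chromosome system
#' (`system_age` Ma). A lineage that never carried the system has
#' `retention_T = 0`; one that still carries it has
#' `retention_T = system_age`.
#'
#' @param lineages data.frame with columns `lineage` (tag or tip label),
#'   `alpha` (>= 1) and `retention_T` (Myr, in `[0, system_age]`), or a named
#'   list of `list(alpha=, retention_T=)` entries.
#' @param system_age age of the sex chromosome system in Ma (e.g. 170 for the
#'   squamate design, 180 for the mammal design).
#' @param scenario_id optional identifier.
#' @return object of class `lineage_scenario`.
#' @export
lineage_scenario <- function(lineages, system_age, scenario_id = NA_character_) {
  if (is.list(lineages) && !is.data.frame(lineages)) {
    lineages <- data.frame(
      lineage = names(lineages),
      alpha = vapply(lineages, function(x) x$alpha, 0),
      retention_T = vapply(lineages, function(x) x$retention_T, 0),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(lineages),
            all(c("lineage", "alpha", "retention_T") %in% names(lineages)))
  if (any(lineages$alpha < 1)) stop("alpha must be >= 1 for every lineage")
  if (any(lineages$retention_T < 0 | lineages$retention_T > system_age))
    stop("retention_T must lie in [0, system_age]")
  structure(list(lineages = lineages, system_age = system_age,
                 scenario_id = scenario_id),
            class = "lineage_scenario")
}

#' @export
print.lineage_scenario <- function(x, ...) {
  cat("Scenario", if (!is.na(x$scenario_id)) x$scenario_id else "",
      "(system age", x$system_age, "Ma)\n")
  print(x$lineages, row.names = FALSE)
  invisible(x)
}

#' Grid of retention scenarios for the turnover scan
#'
#' Builds the null scenario (`retention_T = 0` for the focal lineages) plus
#' one alternative per `step` Myr of retention up to `t_max`: the focal
#' lineages are modeled as X-linked for an increasing number of Myr and as
#' autosomal for the remainder. Non-focal lineages with a fixed history (e.g.
#' a group that always retained the system, or one never exposed) are passed
#' through `fixed` and repeated unchanged in every scenario.
#'
#' `t_max` defaults to `system_age`; the published designs cap it at the age
#' of the focal lineage itself (a lineage cannot have retained the system for
#' longer than it has existed), which is how the squamate design arrives at
#' 16 scenarios for a 170-Myr-old system and the mammal design at 18 for a
#' 180-Myr-old one (see [squamate_design()], [mammal_design()]).
#'
#' @param focal character vector of focal lineage tags.
#' @param alphas numeric alpha per focal lineage (recycled if length 1).
#' @param system_age system age in Ma.
#' @param step grid step in Myr; must divide `t_max`.
#' @param t_max largest retention time on the grid (Myr).
#' @param fixed optional data.frame of non-varying lineages
#'   (`lineage, alpha, retention_T`).
#' @return list of [lineage_scenario()] ordered by retention time, ids
#'   `"T000", "T010", ...`.
#' @export
scenario_grid <- function(focal, alphas, system_age, step = 10,
                          t_max = system_age, fixed = NULL) {
  stopifnot(length(focal) >= 1, t_max <= system_age, t_max >= 0, step > 0)
  if (t_max %% step != 0) stop("step must divide t_max")
  alphas <- rep_len(alphas, length(focal))
  ts <- seq(0, t_max, by = step)
  lapply(ts, function(T) {
    df <- data.frame(lineage = focal, alpha = alphas, retention_T = T,
                     stringsAsFactors = FALSE)
    if (!is.null(fixed)) df <- rbind(df, fixed[, names(df)])
    lineage_scenario(df, system_age = system_age,
                     scenario_id = sprintf("T%03d", T))
  })
}

#' Published scenario grid designs
#'
#' `squamate_design()` reproduces the squamate scan: a 170-Myr-old XY system,
#' agamid lineages scanned from 0 to 150 Myr of retention (16 scenarios; the
#' agamid lineage split from pleurodonts roughly 160-150 Ma, capping its
#' possible retention), snakes never exposed and pleurodonts always X-linked
#' under alpha = 6. `mammal_design()` reproduces the placental scan: a
#' 180-Myr-old system, platypus scanned from 0 to 170 Myr of retention under
#' alpha = 2.9 (18 scenarios; the platypus lineage is ~175 Myr old).
#'
#' @param focal focal lineage tags (default `"agamid"` / `"platypus"`).
#' @param alpha alpha applied to the focal lineages while X-linked.
#' @return list of [lineage_scenario()].
#' @export
squamate_design <- function(focal = "agamid", alpha = 4) {
  scenario_grid(focal, alpha, system_age = 170, step = 10, t_max = 150,
                fixed = data.frame(lineage = "pleurodont", alpha = 6,
                                   retention_T = 170))
}

#' @rdname squamate_design
#' @export
mammal_design <- function(focal = "platypus", alpha = 2.9) {
  scenario_grid(focal, alpha, system_age = 180, step = 10, t_max = 170,
                fixed = data.frame(lineage = "placental", alpha = 4,
                                   retention_T = 180))
}

## Internal: for one tip, Myr age span of every edge on its root path.
## Ages run from 0 at the tip upwards along that tip's own path.
tip_edge_age_spans <- function(tree, myr, tip_id) {
  path <- path_edges_to_root(tree, tip_id)      # tip-upwards
  lens <- myr[path]
  hi <- cumsum(lens)
  lo <- c(0, hi[-length(hi)])
  data.frame(edge = path, age_lo = lo, age_hi = hi)
}

#' Apply a retention scenario to a substitution-scaled tree
#'
#' Shortens branch lengths to emulate the reduced substitution rate of
#' X-linked sequences. For each focal tip the total deficit
#' [mmb_shortening()]`(alpha, retention_T)` is distributed along its
#' root-to-tip path over the time window `[system_age - retention_T,
#' system_age]` Ma, proportionally to the Myr each branch overlaps that
#' window. Branches ancestral to several focal tips are shortened at the
#' deficit rate of the mean alpha of their focal descendants, applied to the
#' mean window overlap. Branches driven below the calibration's clamp floor
#' are clamped there, with the clamped amount reported in attribute
#' `clamp_report`.
#'
#' @param tree a `species_tree` in `"subs"` units produced by
#'   [myr_to_substitutions()] (it must carry the original Myr lengths).
#' @param scenario a [lineage_scenario()].
#' @param calib a [rate_calibration()].
#' @return the shortened tree (attributes preserved; `scenario_id` attached).
#' @export
apply_scenario <- function(tree, scenario, calib = rate_calibration()) {
  if (tree_units(tree) != "subs") stop("tree must be in substitutions units")
  myr <- attr(tree, "myr_lengths")
  if (is.null(myr))
    stop("tree lacks Myr lengths; produce it with myr_to_substitutions()")
  ne <- nrow(tree$edge)
  ntip <- ape::Ntip(tree)

  ## per focal tip: alpha, retention window, edge overlaps
  tip_alpha <- rep(NA_real_, ntip)
  ovl <- matrix(0, nrow = ne, ncol = ntip)   # Myr overlap of edge x tip window
  below <- matrix(FALSE, nrow = ne, ncol = ntip)
  for (k in seq_len(nrow(scenario$lineages))) {
    row <- scenario$lineages[k, ]
    tips <- lineage_tips(tree, row$lineage)
    w_hi <- scenario$system_age
    w_lo <- scenario$system_age - row$retention_T
    for (tl in tips) {
      tid <- match(tl, tree$tip.label)
      if (!is.na(tip_alpha[tid]))
        stop("tip '", tl, "' appears in more than one scenario lineage")
      tip_alpha[tid] <- row$alpha
      spans <- tip_edge_age_spans(tree, myr, tid)
      below[spans$edge, tid] <- TRUE
      if (row$retention_T > 0) {
        o <- pmax(0, pmin(spans$age_hi, w_hi) - pmax(spans$age_lo, w_lo))
        ovl[spans$edge, tid] <- o
      }
    }
  }

  delta <- numeric(ne)
  for (e in seq_len(ne)) {
    tids <- which(below[e, ])
    if (length(tids) == 0L) next
    abar <- mean(tip_alpha[tids])
    obar <- mean(ovl[e, tids])
    if (obar > 0)
      delta[e] <- (mmb_shortening(abar, 10, calib) / 10) * obar
  }

  newlen <- tree$edge.length - delta
  clamped <- newlen < calib$clamp_floor & delta > 0
  clamp_amount <- numeric(ne)
  if (any(clamped)) {
    clamp_amount[clamped] <- calib$clamp_floor - newlen[clamped]
    newlen[clamped] <- calib$clamp_floor
    warning(sum(clamped), " branch(es) clamped to the floor of ",
            calib$clamp_floor, " subs/site")
  }
  tree$edge.length <- newlen
  attr(tree, "scenario_id") <- scenario$scenario_id
  attr(tree, "clamp_report") <- data.frame(edge = which(clamped),
                                           clamped_by = clamp_amount[clamped])
  tree
}

#' Write a scenario grid as TSV
#'
#' One row per (scenario, lineage): `scenario_id`, `lineage`, `alpha`,
#' `retention_T`.
#'
#' @param grid list of [lineage_scenario()].
#' @param file output path.
#' @param ... passed to [write_tsv_report()].
#' @export
write_scenario_grid <- function(grid, file, ...) {
  tab <- do.call(rbind, lapply(grid, function(s)
    cbind(scenario_id = s$scenario_id, s$lineages)))
  write_tsv_report(tab, file, ...)
  invisible(tab)
}
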