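#' Built-in colonization scenarios
#'
#' Six demographic scenarios for the origin of Italian Podolian cattle,
#' over five sampled populations -- Asian indicine (IND), non-Podolian
#' European taurine (NPT), Italian Podolian (ITP), Balkan Podolian (BKP)
#' and South-East Mediterranean Podolian (SEP) -- plus their taurine stem
#' (TAU). All scenarios share: a deep taurine/indicine split at `t3`,
#' domestication bottlenecks ending at `tdt` (taurine) and `tdi`
#' (indicine), an indicine introgression pulse into the taurine stem at
#' `ta` with proportion `ra`, a split of the NPT lineage from the stem at
#' `tD`, and splits of BKP and SEP from the stem at `t1`. They differ in
#' two respects:
#'
#' * wave structure: scenarios 1-3 ("set 1", two waves) place the NPT
#'   split before the introgression (`tD >= ta`), so NPT carries no
#'   indicine ancestry; scenarios 4-6 ("set 2", one wave) place it after
#'   (`ta >= tD`), nesting NPT within a single colonization wave;
#' * route of the Italian Podolian: Mediterranean (1, 4) -- ITP splits
#'   from SEP at `ta1` with a founder-effect size reduction; Balkan (2, 5)
#'   -- ITP splits from BKP at `ta1`, no forced founder reduction;
#'   admixture (3, 6) -- ITP is formed at `ta1` as a mixture of BKP
#'   (proportion `r`) and SEP (`1 - r`).
#'
#' @return List of six `scenario_spec` objects.
#' @seealso [draw_params()], [simulate_dataset()]
#' @export
build_builtin_scenarios <- function() {
  mk <- function(id, set, route) {
    s <- list(id = id, set = set, route = route,
              populations = scenario_populations(),
              description = sprintf("Scenario %d (%s wave%s - %s route)",
                                    id, if (set == 1) "two" else "one",
                                    if (set == 1) "s" else "", route))
    class(s) <- "scenario_spec"
    s
  }
  list(mk(1L, 1L, "mediterranean"), mk(2L, 1L, "balkan"),
       mk(3L, 1L, "admixture"),
       mk(4L, 2L, "mediterranean"), mk(5L, 2L, "balkan"),
       mk(6L, 2L, "admixture"))
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(x$description, "\n")
  invisible(x)
}

# population index order used throughout the simulation engine
scenario_populations <- function() c("IND", "NPT", "ITP", "BKP", "SEP", "TAU")

#' Default parameter priors
#'
#' Uniform priors in generations (times) and diploid individuals (sizes).
#' The taurine domestication time `tdt` carries the internal calibration
#' bound of 3600 to 7800 generations; remaining priors are broad defaults
#' documented in the methods vignette and overridable per element.
#'
#' @param ... named `c(lower, upper)` overrides, e.g.
#'   `tD = c(100, 5000)`.
#' @return A named list of `c(lower, upper)` bounds of class `prior_spec`.
#' @export
default_priors <- function(...) {
  pr <- list(
    N1 = c(100, 50000), N2 = c(100, 50000), N3 = c(100, 50000),
    N4 = c(100, 50000), N4b = c(100, 50000), N5 = c(100, 50000),
    N5b = c(100, 50000),
    t3 = c(80000, 120000),
    tdt = c(3600, 7800),
    tdi = c(1600, 7800),
    tD = c(10, 7800), ta = c(10, 7800), t1 = c(10, 7800), ta1 = c(10, 7800),
    r = c(0.05, 0.95), ra = c(0.05, 0.95),
    bn_size_t = c(50, 2000), bn_dur_t = c(2, 50),
    bn_size_i = c(50, 2000), bn_dur_i = c(2, 50),
    bn_size_f = c(50, 2000), bn_dur_f = c(2, 50)
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (!nm %in% names(pr)) stop("unknown prior parameter: ", nm)
    stopifnot(length(ov[[nm]]) == 2L, ov[[nm]][1] < ov[[nm]][2])
    pr[[nm]] <- ov[[nm]]
  }
  class(pr) <- "prior_spec"
  pr
}

#' Draw one parameter vector from the priors
#'
#' Sizes, `t3`, `tdi`, admixture proportions and bottleneck parameters are
#' drawn independently. The calibration time `tdt` is drawn first from its
#' own uniform prior; the four more recent times are then drawn by
#' rejection from their priors truncated at `tdt` until they satisfy the
#' scenario set's ordering (set 1: `tdt >= tD >= ta >= t1 >= ta1`; set 2:
#' `tdt >= ta >= tD >= t1 >= ta1`), which keeps the `tdt` marginal exactly
#' uniform.
#'
#' @param priors a `prior_spec` from [default_priors()].
#' @param scenario a `scenario_spec` (only its `set` matters here).
#' @return Named numeric vector of class `param_vector`.
#' @export
draw_params <- function(priors, scenario) {
  runi <- function(nm, upper = NULL) {
    b <- priors[[nm]]
    if (!is.null(upper)) b[2] <- min(b[2], upper)
    stats::runif(1, b[1], b[2])
  }
  p <- c(N1 = runi("N1"), N2 = runi("N2"), N3 = runi("N3"),
         N4 = runi("N4"), N4b = runi("N4b"), N5 = runi("N5"),
         N5b = runi("N5b"),
         t3 = runi("t3"), tdt = runi("tdt"), tdi = runi("tdi"))
  repeat {
    tt <- c(tD = runi("tD", p[["tdt"]]), ta = runi("ta", p[["tdt"]]),
            t1 = runi("t1", p[["tdt"]]), ta1 = runi("ta1", p[["tdt"]]))
    ord <- if (scenario$set == 1L)
      tt[["tD"]] >= tt[["ta"]] && tt[["ta"]] >= tt[["t1"]] &&
        tt[["t1"]] >= tt[["ta1"]]
    else
      tt[["ta"]] >= tt[["tD"]] && tt[["tD"]] >= tt[["t1"]] &&
        tt[["t1"]] >= tt[["ta1"]]
    if (ord) break
  }
  p <- c(p, tt,
         r = runi("r"), ra = runi("ra"),
         bn_size_t = runi("bn_size_t"), bn_dur_t = runi("bn_dur_t"),
         bn_size_i = runi("bn_size_i"), bn_dur_i = runi("bn_dur_i"),
         bn_size_f = runi("bn_size_f"), bn_dur_f = runi("bn_dur_f"))
  class(p) <- "param_vector"
  p
}

#' Backward-in-time event schedule for a scenario
#'
#' Expands a scenario and one parameter draw into the sorted event matrix
#' and initial population sizes consumed by the coalescent engine. Exposed
#' mainly for inspection and testing.
#'
#' @param scenario a `scenario_spec`.
#' @param params a `param_vector` from [draw_params()].
#' @return List with `events` (matrix with columns time, type, a, b, c, x;
#'   0-based population indices), `sizes0` (initial diploid sizes) and
#'   `populations` (label order).
#' @export
scenario_events <- function(scenario, params) {
  p <- as.list(unclass(params))
  pops <- scenario_populations()
  i <- function(nm) match(nm, pops) - 1L       # 0-based for the engine
  IND <- i("IND"); NPT <- i("NPT"); ITP <- i("ITP")
  BKP <- i("BKP"); SEP <- i("SEP"); TAU <- i("TAU")

  sizes0 <- c(p$N1, p$N2,
              if (scenario$route == "mediterranean") p$N5b else p$N4b,
              p$N4, p$N5, p$N3)

  ev <- list()
  add <- function(time, type, a, b = 0, cc = 0, x = 0)
    ev[[length(ev) + 1L]] <<- c(time, type, a, b, cc, x)

  # Italian Podolian origin at ta1
  if (scenario$route == "mediterranean") {
    t_f <- p$ta1 - p$bn_dur_f
    if (t_f > 0) add(t_f, 0, ITP, x = p$bn_size_f)
    else sizes0[ITP + 1L] <- p$bn_size_f       # founded within the bottleneck
    add(p$ta1, 1, ITP, SEP)
  } else if (scenario$route == "balkan") {
    add(p$ta1, 1, ITP, BKP)
  } else {
    add(p$ta1, 2, ITP, BKP, SEP, p$r)
  }

  # Balkan and South-East Podolian join the taurine stem at t1
  add(p$t1, 1, BKP, TAU)
  add(p$t1, 1, SEP, TAU)

  # indicine introgression pulse into the stem at ta
  add(p$ta, 2, TAU, IND, TAU, p$ra)

  # non-Podolian taurine split at tD (before ta in set 1, after in set 2)
  add(p$tD, 1, NPT, TAU)

  # domestication bottlenecks (more recent edge at t - duration)
  add(max(p$tdt - p$bn_dur_t, 1e-6), 0, TAU, x = p$bn_size_t)
  add(p$tdt, 0, TAU, x = p$N3)
  add(max(p$tdi - p$bn_dur_i, 1e-6), 0, IND, x = p$bn_size_i)
  add(p$tdi, 0, IND, x = p$N1)

  # deep taurine/indicine split
  add(p$t3, 1, IND, TAU)

  E <- do.call(rbind, ev)
  E <- E[order(E[, 1]), , drop = FALSE]
  colnames(E) <- c("time", "type", "a", "b", "c", "x")
  list(events = E, sizes0 = sizes0, populations = pops)
}

#' Check that a scenario funnels all lineages into one root
#'
#' Walks the event schedule and verifies that every sampled population is
#' eventually merged (directly or transitively) into a single surviving
#' population, so the coalescent cannot get stuck.
#'
#' @param scenario a `scenario_spec`.
#' @param params a `param_vector`.
#' @return `TRUE` (invisibly) or an error describing the defect.
#' @export
validate_scenario <- function(scenario, params) {
  se <- scenario_events(scenario, params)
  pops <- se$populations
  alive <- rep(TRUE, length(pops))
  E <- se$events
  for (k in seq_len(nrow(E))) {
    type <- E[k, "type"]
    a <- E[k, "a"] + 1L; b <- E[k, "b"] + 1L; cc <- E[k, "c"] + 1L
    if (type == 1) {
      if (!alive[a]) stop("merge from an already-merged population: ", pops[a])
      if (!alive[b]) stop("merge into an already-merged population: ", pops[b])
      alive[a] <- FALSE
    } else if (type == 2) {
      if (!alive[a] || !alive[b] || !alive[cc])
        stop("admixture involving a merged population at t = ", E[k, "time"])
      if (cc != a) alive[a] <- FALSE
      pr <- E[k, "x"]
      if (pr < 0 || pr > 1) stop("admixture proportion outside [0, 1]")
    }
  }
  if (sum(alive) != 1L)
    stop("schedule leaves ", sum(alive), " populations unmerged")
  invisible(TRUE)
}

#' Serialize / deserialize a scenario as YAML
#'
#' The YAML form lists the scenario's events with population labels and
#' parameter names (not values), making the demographic structure
#' reviewable as text.
#'
#' @param scenario a `scenario_spec`.
#' @param path optional file to write to.
#' @return `scenario_to_yaml`: the YAML string (invisibly if written to
#'   `path`); `scenario_from_yaml`: a `scenario_spec`.
#' @export
scenario_to_yaml <- function(scenario, path = NULL) {
  origin <- switch(scenario$route,
    mediterranean = list(event = "split", derived = "ITP", ancestral = "SEP",
                         time = "ta1", founder_bottleneck = TRUE),
    balkan = list(event = "split", derived = "ITP", ancestral = "BKP",
                  time = "ta1", founder_bottleneck = FALSE),
    admixture = list(event = "admixture", target = "ITP",
                     sources = c("BKP", "SEP"), proportion = "r",
                     time = "ta1"))
  doc <- list(
    id = scenario$id, set = scenario$set, route = scenario$route,
    populations = scenario$populations,
    events = list(
      italian_podolian_origin = origin,
      podolian_splits = list(event = "split", derived = c("BKP", "SEP"),
                             ancestral = "TAU", time = "t1"),
      indicine_introgression = list(event = "admixture", target = "TAU",
                                    sources = c("IND", "TAU"),
                                    proportion = "ra", time = "ta"),
      nonpodolian_split = list(event = "split", derived = "NPT",
                               ancestral = "TAU", time = "tD"),
      taurine_domestication = list(event = "bottleneck", population = "TAU",
                                   time = "tdt", size = "bn_size_t",
                                   duration = "bn_dur_t"),
      indicine_domestication = list(event = "bottleneck", population = "IND",
                                    time = "tdi", size = "bn_size_i",
                                    duration = "bn_dur_i"),
      taurine_indicine_split = list(event = "split", derived = "IND",
                                    ancestral = "TAU", time = "t3")
    )
  )
  txt <- yaml::as.yaml(doc)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname scenario_to_yaml
#' @param text YAML string (or `path` to read from).
#' @export
scenario_from_yaml <- function(text = NULL, path = NULL) {
  doc <- if (!is.null(path)) yaml::read_yaml(path) else yaml::yaml.load(text)
  s <- list(id = as.integer(doc$id), set = as.integer(doc$set),
            route = doc$route, populations = unlist(doc$populations),
            description = sprintf("Scenario %d (%s wave%s - %s route)",
                                  doc$id, if (doc$set == 1) "two" else "one",
                                  if (doc$set == 1) "s" else "", doc$route))
  class(s) <- "scenario_spec"
  s
}
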