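# Synthetic-cohort ground truth. The real 480-patient ablation registry is
# private; what is public is its stratified count table (per variable
# class: total, relapsed, AF-free). The generator builds a full Bayesian
# network over the default schema whose marginals reproduce those counts
# exactly by construction, whose conditional dependencies follow the
# published graph, and whose outcome CPT is an additive-log-odds surrogate
# calibrated so the implied per-class relapse rates match the stratified
# counts. Everything downstream (structure recovery, parameter recovery,
# the validation protocol) is exercised against this ground truth.

#' Load the stratified count fixture
#'
#' Per variable class: total patients, how many relapsed, how many stayed
#' AF-free — 480 patients, 166 relapses. Rows for the `false` level of
#' binary comorbidities are complements of the printed `true` rows.
#'
#' @param path Fixture CSV; defaults to the packaged copy.
#' @return data.frame of class `bnaf_table1` with columns `variable`,
#'   `class`, `total`, `relapse`, `af_free`.
#' @export
load_table1_fixture <- function(path = system.file("extdata",
                                                   "table1_counts.csv",
                                                   package = "bnaf")) {
  df <- utils::read.csv(path, colClasses = c("character", "character",
                                             "integer", "integer", "integer"))
  stopifnot(all(df$total == df$relapse + df$af_free))
  class(df) <- c("bnaf_table1", "data.frame")
  df
}

fixture_marginal <- function(fixture, variable, schema) {
  states <- schema_states(schema, variable)
  rows <- fixture[fixture$variable == variable, ]
  p <- rows$total[match(states, rows$class)] / sum(rows$total)
  stats::setNames(p, states)
}

fixture_relapse_rate <- function(fixture, variable, schema) {
  states <- schema_states(schema, variable)
  rows <- fixture[fixture$variable == variable, ]
  stats::setNames(rows$relapse[match(states, rows$class)] /
                    rows$total[match(states, rows$class)], states)
}

#' The ground-truth network structure
#'
#' The knowledge-driven whitelist arcs plus the data-driven arc set
#' (sex into smoking / alcoholism / BMI, BMI into epicardial fat, OSA into
#' preablation AF type, AF type into left-atrial volume), as a DAG over
#' the default schema.
#'
#' @param constraints A `bnaf_constraints`; defaults to the packaged file.
#' @param calibration_path Generator calibration JSON carrying the
#'   learned-arc set.
#' @return A `bnaf_structure`.
#' @export
ground_truth_structure <- function(constraints = default_constraints(),
                                   calibration_path =
                                     system.file("extdata",
                                                 "generator_calibration.json",
                                                 package = "bnaf")) {
  cal <- jsonlite::read_json(calibration_path, simplifyVector = TRUE,
                             simplifyMatrix = TRUE)
  schema <- build_default_schema()
  network_structure(schema_names(schema),
                    arcs = rbind(constraints$whitelist,
                                 as_arc_matrix(cal$learned_arcs)),
                    whitelist = constraints$whitelist,
                    blacklist = constraints$blacklist)
}

# solve P(child = positive | group) columns so the child's marginal matches
# the fixture exactly, given an anchor for one group
solve_binary_conditional <- function(target_marginal, group_probs, anchored) {
  free <- setdiff(names(group_probs), names(anchored))
  stopifnot(length(free) == 1L)
  p_free <- (target_marginal -
               sum(group_probs[names(anchored)] * unlist(anchored))) /
    group_probs[[free]]
  if (p_free < 0 || p_free > 1) {
    stop("infeasible calibration: solved P(.|", free, ") = ",
         round(p_free, 4), " outside [0, 1]", call. = FALSE)
  }
  out <- c(unlist(anchored), stats::setNames(p_free, free))
  out[names(group_probs)]
}

# same, for a multi-state child: one free group column, the rest anchored
solve_categorical_conditional <- function(target_marginal, group_probs,
                                          anchored_cols) {
  free <- setdiff(names(group_probs), names(anchored_cols))
  stopifnot(length(free) == 1L)
  acc <- target_marginal
  for (g in names(anchored_cols)) {
    acc <- acc - group_probs[[g]] * anchored_cols[[g]]
  }
  col_free <- acc / group_probs[[free]]
  if (any(col_free < 0) || abs(sum(col_free) - 1) > 1e-6) {
    stop("infeasible calibration: solved column for '", free,
         "' is not a probability vector (",
         paste(round(col_free, 4), collapse = ", "), ")", call. = FALSE)
  }
  out <- anchored_cols
  out[[free]] <- col_free / sum(col_free)
  out[names(group_probs)]
}

# intercept of a logistic CPT so the implied marginal hits the target
solve_logistic_intercept <- function(target, config_probs, effects) {
  f <- function(b0) sum(config_probs * stats::plogis(b0 + effects)) - target
  stats::uniroot(f, c(-20, 20), tol = 1e-12)$root
}

make_cpt_binary <- function(schema, child, parents, p_true) {
  # p_true: vector over parent configurations (first parent fastest)
  card <- schema_cardinalities(schema)
  dims <- c(2L, if (length(parents)) unname(card[parents]))
  dn <- c(list(schema_states(schema, child)),
          lapply(parents, function(p) schema_states(schema, p)))
  names(dn) <- c(child, parents)
  cpt(child, parents, array(rbind(1 - p_true, p_true), dims, dn))
}

make_cpt_categorical <- function(schema, child, parents, cols) {
  # cols: matrix r x q of state probabilities per parent configuration
  card <- schema_cardinalities(schema)
  dims <- c(nrow(cols), if (length(parents)) unname(card[parents]))
  dn <- c(list(schema_states(schema, child)),
          lapply(parents, function(p) schema_states(schema, p)))
  names(dn) <- c(child, parents)
  cpt(child, parents, array(cols, dims, dn))
}

#' Build the calibrated ground-truth network
#'
#' Constructs one CPT per node such that (a) every variable's marginal
#' distribution equals the fixture's class frequencies exactly;
#' (b) the conditional dependencies (who smokes more, how strongly BMI
#' drives epicardial fat, ...) follow the anchor values in the calibration
#' file, with the remaining conditional columns solved from the margins;
#' (c) the outcome CPT over its 7 parents is an additive-log-odds model
#' iteratively calibrated until the implied relapse rate within each
#' parent class matches the fixture's stratified rate. Deterministic given
#' the fixture and calibration file; infeasible targets raise an error
#' naming the offending margin rather than silently distorting it.
#'
#' @param fixture A [load_table1_fixture()] table.
#' @param structure The generating DAG, by default
#'   [ground_truth_structure()].
#' @param calibration_path Calibration JSON path.
#' @param tol Convergence tolerance on the stratified relapse rates.
#' @return A `bnaf_fitted` ground-truth network (usable everywhere a
#'   fitted network is).
#' @export
build_ground_truth <- function(fixture = load_table1_fixture(),
                               structure = ground_truth_structure(),
                               calibration_path =
                                 system.file("extdata",
                                             "generator_calibration.json",
                                             package = "bnaf"),
                               tol = 1e-8) {
  cal <- jsonlite::read_json(calibration_path, simplifyVector = TRUE,
                             simplifyMatrix = TRUE)
  schema <- build_default_schema()
  stopifnot(setequal(structure$nodes, schema_names(schema)))
  an <- cal$anchors
  marg <- function(v) fixture_marginal(fixture, v, schema)
  p_sex <- marg("sex"); p_age <- marg("age")

  cpts <- list()
  cpts$sex <- make_cpt_categorical(schema, "sex", character(0L),
                                   matrix(p_sex, ncol = 1L))
  cpts$age <- make_cpt_categorical(schema, "age", character(0L),
                                   matrix(p_age, ncol = 1L))

  # binaries driven by sex: anchor the male column, solve the female one
  smoking <- solve_binary_conditional(marg("smoking")[["true"]], p_sex,
                                      list(male = an$smoking_given_male))
  cpts$smoking <- make_cpt_binary(schema, "smoking", "sex", smoking)
  alco <- solve_binary_conditional(marg("alcoholism")[["true"]], p_sex,
                                   list(male = an$alcoholism_given_male))
  cpts$alcoholism <- make_cpt_binary(schema, "alcoholism", "sex", alco)

  # BMI class by sex: anchor the male column
  bmi_cols <- solve_categorical_conditional(
    marg("bmi"), p_sex, list(male = an$bmi_given_male))
  cpts$bmi <- make_cpt_categorical(schema, "bmi", "sex",
                                   do.call(cbind, bmi_cols))
  p_bmi <- marg("bmi")  # matched exactly by construction

  # comorbidities with logistic CPTs; intercept solved against the margin.
  # age and bmi are marginally independent (different root ancestries).
  grid_ab <- expand.grid(age = seq_len(3L), bmi = seq_len(3L))
  w_ab <- p_age[grid_ab$age] * p_bmi[grid_ab$bmi]
  for (child in c("diabetes", "hbp")) {
    eff <- cal$logistic_effects[[child]]
    e <- eff$age[grid_ab$age] + eff$bmi[grid_ab$bmi]
    b0 <- solve_logistic_intercept(marg(child)[["true"]], w_ab, e)
    # CPT parent order must match the structure's arc order
    pars <- parents_of(structure, child)
    p_true <- if (identical(pars, c("bmi", "age"))) {
      grid <- expand.grid(bmi = seq_len(3L), age = seq_len(3L))
      stats::plogis(b0 + eff$age[grid$age] + eff$bmi[grid$bmi])
    } else {
      grid <- expand.grid(age = seq_len(3L), bmi = seq_len(3L))
      stats::plogis(b0 + eff$age[grid$age] + eff$bmi[grid$bmi])
    }
    cpts[[child]] <- make_cpt_binary(schema, child, pars, p_true)
  }
  eff_osa <- cal$logistic_effects$osa$bmi
  b0 <- solve_logistic_intercept(marg("osa")[["true"]], p_bmi, eff_osa)
  p_osa_bmi <- stats::plogis(b0 + eff_osa)
  cpts$osa <- make_cpt_binary(schema, "osa", "bmi", p_osa_bmi)
  p_osa <- sum(p_bmi * p_osa_bmi)

  # AF type by OSA: anchor the OSA-positive column
  af <- solve_binary_conditional(marg("af_type")[["persistent"]],
                                 c(false = 1 - p_osa, true = p_osa),
                                 list(true = an$persistent_given_osa_true))
  cpts$af_type <- make_cpt_binary(schema, "af_type", "osa", af)
  p_persistent <- marg("af_type")[["persistent"]]

  # LA volume by AF type: anchor the persistent column
  la_cols <- solve_categorical_conditional(
    marg("la_volume"),
    c(paroxysmal = 1 - p_persistent, persistent = p_persistent),
    list(persistent = an$la_volume_given_persistent))
  cpts$la_volume <- make_cpt_categorical(schema, "la_volume", "af_type",
                                         do.call(cbind, la_cols))

  # epicardial fat by BMI: anchor the normal and obese columns
  fat_cols <- solve_categorical_conditional(
    marg("epicardial_fat"), p_bmi,
    list(normal = an$epicardial_fat_given_bmi_normal,
         obese = an$epicardial_fat_given_bmi_obese))
  cpts$epicardial_fat <- make_cpt_categorical(schema, "epicardial_fat", "bmi",
                                              do.call(cbind, fat_cols))

  # ---- outcome CPT: additive log-odds calibrated to stratified rates ----
  outcome <- schema$outcome
  parents <- parents_of(structure, outcome)
  card <- schema_cardinalities(schema)

  # exact joint over the 7 parents, via enumeration of the predictor
  # subnetwork (every non-outcome CPT is already defined)
  predictors <- setdiff(schema_names(schema), outcome)
  pred_cells <- joint_cells_generic(card[predictors])
  colnames(pred_cells) <- predictors
  pj <- rep(1, nrow(pred_cells))
  for (node in predictors) {
    ct <- cpts[[node]]
    idx <- pred_cells[, node]
    mult <- card[[node]]
    for (p in ct$parents) {
      idx <- idx + mult * (pred_cells[, p] - 1L)
      mult <- mult * card[[p]]
    }
    pj <- pj * as.numeric(ct$prob)[idx]
  }
  # weight of each parent configuration (first parent fastest)
  pidx <- rep(1L, nrow(pred_cells))
  mult <- 1L
  for (p in parents) {
    pidx <- pidx + mult * (pred_cells[, p] - 1L)
    mult <- mult * card[[p]]
  }
  q <- as.integer(mult)
  w <- numeric(q)
  agg <- rowsum(pj, pidx)
  w[as.integer(rownames(agg))] <- agg
  cfg <- joint_cells_generic(card[parents])
  colnames(cfg) <- parents

  targets <- lapply(parents, function(v) fixture_relapse_rate(fixture, v, schema))
  names(targets) <- parents
  overall <- sum(fixture[fixture$variable == "relapse", "relapse"]) /
    sum(fixture[fixture$variable == "relapse", "total"])

  b0 <- stats::qlogis(overall)
  beta <- lapply(parents, function(v) {
    stats::qlogis(targets[[v]]) - stats::qlogis(overall)
  })
  names(beta) <- parents
  rate_of <- function() {
    eta <- rep(b0, q)
    for (v in parents) eta <- eta + beta[[v]][cfg[, v]]
    stats::plogis(eta)
  }
  for (it in seq_len(500L)) {
    p <- rate_of()
    worst <- 0
    for (v in parents) {
      for (k in seq_along(targets[[v]])) {
        sel <- cfg[, v] == k
        implied <- sum(w[sel] * p[sel]) / sum(w[sel])
        worst <- max(worst, abs(implied - targets[[v]][[k]]))
        beta[[v]][k] <- beta[[v]][k] +
          stats::qlogis(targets[[v]][[k]]) - stats::qlogis(implied)
      }
      p <- rate_of()
    }
    implied_all <- sum(w * p)
    b0 <- b0 + stats::qlogis(overall) - stats::qlogis(implied_all)
    if (worst < tol) break
  }
  p <- rate_of()
  # final feasibility audit: report any unmatched stratified margin
  unmatched <- character(0L)
  for (v in parents) for (k in seq_along(targets[[v]])) {
    sel <- cfg[, v] == k
    implied <- sum(w[sel] * p[sel]) / sum(w[sel])
    if (abs(implied - targets[[v]][[k]]) > 1e-4) {
      unmatched <- c(unmatched, sprintf("%s=%s (implied %.4f, target %.4f)",
                                        v, schema_states(schema, v)[k],
                                        implied, targets[[v]][[k]]))
    }
  }
  if (length(unmatched)) {
    stop("outcome calibration could not match: ",
         paste(unmatched, collapse = "; "), call. = FALSE)
  }
  cpts[[outcome]] <- make_cpt_binary(schema, outcome, parents, p)

  cpts <- cpts[structure$nodes]
  gt <- structure(list(structure = structure, cpts = cpts, ess = NA_real_,
                       schema = schema, fixture = fixture,
                       outcome_coefficients = list(intercept = b0,
                                                   effects = beta)),
                  class = c("bnaf_ground_truth", "bnaf_fitted"))
  gt
}

#' Sample a synthetic cohort from a ground-truth network
#'
#' Ancestral sampling: each node is drawn in topological order conditional
#' on its sampled parents. Deterministic given the seed; rows i.i.d.
#'
#' @param config A `bnaf_fitted` (typically [build_ground_truth()]).
#' @param n Number of patients (default 480, the registry size).
#' @param seed Integer seed (mandatory).
#' @return A cohort.
#' @export
sample_cohort <- function(config, n = 480L, seed) {
  stopifnot(n >= 1L)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  schema <- config$schema
  card <- schema_cardinalities(schema)
  order <- topological_order(config$structure)
  codes <- matrix(0L, n, length(card),
                  dimnames = list(NULL, schema_names(schema)))
  for (node in order) {
    ct <- config$cpts[[node]]
    r <- card[[node]]
    q <- prod(dim(as.array(ct$prob))) / r
    pm <- matrix(as.numeric(ct$prob), nrow = r)
    cum <- apply(pm, 2L, cumsum)
    cfg <- rep(1L, n)
    mult <- 1L
    for (p in ct$parents) {
      cfg <- cfg + mult * (codes[, p] - 1L)
      mult <- mult * card[[p]]
    }
    u <- stats::runif(n)
    cm <- t(cum)[cfg, , drop = FALSE]
    codes[, node] <- 1L + as.integer(rowSums(u > cm))
  }
  df <- as.data.frame(lapply(schema_names(schema), function(v) {
    factor(schema_states(schema, v)[codes[, v]],
           levels = schema_states(schema, v))
  }), col.names = schema_names(schema))
  as_cohort(df, schema)
}

# mean total-variation distance between two networks' CPT rows
mean_cpt_tv <- function(net_a, net_b) {
  tvs <- unlist(lapply(net_a$structure$nodes, function(node) {
    a <- as.array(net_a$cpts[[node]]$prob)
    b <- as.array(net_b$cpts[[node]]$prob)
    stopifnot(identical(dim(a), dim(b)) || identical(length(a), length(b)))
    r <- dim(as.array(a))[1L]
    ma <- matrix(as.numeric(a), nrow = r)
    mb <- matrix(as.numeric(b), nrow = r)
    0.5 * colSums(abs(ma - mb))
  }))
  mean(tvs)
}

#' Parameter-recovery benchmark
#'
#' For each sample size: draw a cohort from the ground truth, refit the
#' CPTs on the true structure, and report the mean total-variation
#' distance between generating and refit CPT rows. Consistency of the
#' posterior-mean estimator shows as distance decreasing with n.
#'
#' @param config Ground-truth network.
#' @param n_list Ascending sample sizes.
#' @param seed Integer seed.
#' @param ess Equivalent sample size used in refitting.
#' @return data.frame with columns `n` and `mean_tv`.
#' @export
parameter_recovery_report <- function(config, n_list = c(500L, 5000L, 50000L),
                                      seed = 1L, ess = 1) {
  stopifnot(!is.unsorted(n_list))
  out <- vapply(seq_along(n_list), function(i) {
    cohort <- sample_cohort(config, n_list[[i]], seed = seed + i)
    refit <- fit_cpts(config$structure, cohort, ess = ess)
    mean_cpt_tv(config, refit)
  }, numeric(1L))
  data.frame(n = as.integer(n_list), mean_tv = out)
}

#' Structure-recovery benchmark
#'
#' Samples a cohort from the ground truth and runs constrained hill
#' climbing; reports the learned arc set, its structural Hamming distance
#' to the generating DAG, and whether the BMI - epicardial fat dependence
#' was recovered (in either orientation) — the qualitative data-driven
#' finding the generator is meant to reproduce.
#'
#' @param config Ground-truth network.
#' @param n Sample size (default 20000).
#' @param seed Integer seed.
#' @param constraints Constraints for the search (default: the packaged
#'   whitelist/blacklist, i.e. the greyed knowledge arcs).
#' @return List: `structure`, `shd`, `learned_arcs`, `bmi_fat_recovered`.
#' @export
structure_recovery_report <- function(config, n = 20000L, seed = 1L,
                                      constraints = default_constraints()) {
  cohort <- sample_cohort(config, n, seed = seed)
  learned <- hill_climb(cohort, constraints)
  extra <- learned$arcs[!arc_keys(learned$arcs) %in%
                          arc_keys(constraints$whitelist), , drop = FALSE]
  list(structure = learned,
       shd = structural_hamming_distance(learned, config$structure),
       learned_arcs = extra,
       bmi_fat_recovered = has_arc(learned$arcs, "bmi", "epicardial_fat") ||
         has_arc(learned$arcs, "epicardial_fat", "bmi"))
}

#' Random discrete network
#'
#' Draws a random DAG (uniform topological order, independent arc
#' inclusion) over variables with 2-3 states and fills every CPT with
#' normalized Dirichlet(1) rows. Used to exercise the inference engines
#' against each other on arbitrary small networks.
#'
#' @param n_nodes Number of variables.
#' @param seed Integer seed.
#' @param arc_prob Inclusion probability per ordered pair.
#' @return A `bnaf_fitted`.
#' @export
random_discrete_network <- function(n_nodes, seed, arc_prob = 0.4) {
  set.seed(seed)
  nms <- paste0("v", seq_len(n_nodes))
  card <- sample(2:3, n_nodes, replace = TRUE)
  schema <- domain_schema(lapply(seq_len(n_nodes), function(i) {
    variable_spec(nms[i], paste0("s", seq_len(card[i])))
  }), outcome = nms[n_nodes])
  order <- sample(n_nodes)
  arcs <- NULL
  for (i in seq_len(n_nodes)) for (j in seq_len(n_nodes)) {
    if (which(order == i) < which(order == j) && stats::runif(1) < arc_prob) {
      arcs <- rbind(arcs, c(nms[i], nms[j]))
    }
  }
  st <- network_structure(nms, arcs = if (is.null(arcs)) NULL else arcs)
  cpts <- lapply(nms, function(node) {
    pars <- st$arcs[st$arcs[, 2L] == node, 1L]
    r <- card[match(node, nms)]
    q <- if (length(pars)) prod(card[match(pars, nms)]) else 1L
    m <- matrix(stats::rgamma(r * q, 1), nrow = r)
    m <- sweep(m, 2L, colSums(m), "/")
    dims <- c(r, if (length(pars)) card[match(pars, nms)])
    dn <- c(list(paste0("s", seq_len(r))),
            lapply(pars, function(p) paste0("s", seq_len(card[match(p, nms)]))))
    names(dn) <- c(node, pars)
    cpt(node, pars, array(m, dims, dn))
  })
  names(cpts) <- nms
  fitted_network(st, cpts, schema)
}

#' Generator calibration report
#'
#' Samples a large cohort and compares empirical frequencies with the
#' fixture's calibration targets: every variable's marginal class
#' frequencies, and the outcome-stratified class frequencies of the seven
#' outcome parents (the only variables whose association with relapse the
#' generating graph encodes).
#'
#' @param config Ground-truth network.
#' @param n Sample size (default 200000).
#' @param seed Integer seed.
#' @return data.frame with columns `kind` (`marginal` / `stratified`),
#'   `variable`, `class`, `target`, `empirical`, `abs_error` (all on the
#'   proportion scale).
#' @export
calibration_report <- function(config, n = 200000L, seed = 1L) {
  schema <- config$schema
  fixture <- config$fixture
  if (is.null(fixture)) fixture <- load_table1_fixture()
  cohort <- sample_cohort(config, n, seed = seed)
  outcome <- schema$outcome
  relapsed <- cohort[[outcome]] == "true"
  rows <- list()
  for (v in setdiff(schema_names(schema), outcome)) {
    emp <- table(cohort[[v]]) / n
    tgt <- fixture_marginal(fixture, v, schema)
    for (s in schema_states(schema, v)) {
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "marginal", variable = v, class = s,
        target = tgt[[s]], empirical = as.numeric(emp[[s]]))
    }
  }
  tgt_rel <- sum(fixture[fixture$variable == "relapse", "relapse"]) /
    sum(fixture[fixture$variable == "relapse", "total"])
  rows[[length(rows) + 1L]] <- data.frame(
    kind = "marginal", variable = outcome, class = "true",
    target = tgt_rel, empirical = mean(relapsed))
  for (v in parents_of(config$structure, outcome)) {
    emp <- table(cohort[[v]][relapsed]) / sum(relapsed)
    fr <- fixture[fixture$variable == v, ]
    for (s in schema_states(schema, v)) {
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "stratified", variable = v, class = s,
        target = fr$relapse[fr$class == s] / sum(fr$relapse),
        empirical = as.numeric(emp[[s]]))
    }
  }
  out <- do.call(rbind, rows)
  out$abs_error <- abs(out$target - out$empirical)
  out
}
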