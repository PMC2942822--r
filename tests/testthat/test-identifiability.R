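# Desk-scale identifiability checks run on deliberately tiny topologies:
# full 29-parameter scans are out of test budget, but the mechanism --
# a ridge in parameter space showing up as strong correlation across
# near-optimal multi-start fits -- is scale-free. Scan fits are left
# unpolished on purpose (see ?identifiability_scan): on a practically
# flat ridge the optimizer stalls at scattered points along it, which is
# exactly the diagnostic signal.

toy_topology <- function(edges, compartments) {
  structure(list(compartments = compartments, edges = edges,
                 central = "plasma", cold_influx_sites = character(0)),
            class = "fk_topology")
}

toy_dataset <- function(topo, truth, times, organs, sd_plasma = 5,
                        seed = 1) {
  tr <- simulate_tracer(topo, truth, times)
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_along(times), function(i) {
    data.frame(organ = organs, time = times[i],
               mean = pmax(tr$content[organs, i] *
                             (1 + rnorm(length(organs), 0, 0.05)), 0),
               sd = pmax(0.1 * tr$content[organs, i], 0.05), n = 5)
  }))
  rows$sd[rows$organ == "plasma"] <- sd_plasma
  tracer_dataset(rows)
}

test_that("a freed double exit is flagged as interdependent", {
  # liver has both a reflux and a body-loss exit; refluxed tracer is
  # mostly swallowed by an absorbing second organ, so the liver curve
  # identifies only the SUM of the two exits. Plasma itself is poorly
  # resolved (large SD), mirroring data whose first sample comes long
  # after plasma clearance.
  edges <- data.frame(
    source = c("plasma", "plasma", "liver", "liver"),
    target = c("liver", "organ_b", "plasma", EXTERNAL),
    param = c("kp_liv", "kp_b", "kliv_p", "kliv_out"))
  topo <- toy_topology(edges, c("plasma", "liver", "organ_b"))
  truth <- c(kp_liv = 2, kp_b = 18, kliv_p = 0.1, kliv_out = 0.1)
  ds <- toy_dataset(topo, truth, times = c(2, 4, 7, 14, 21, 28),
                    organs = c("plasma", "liver"), sd_plasma = 50)
  scan <- identifiability_scan(ds, topo, n_starts = 12, seed = 4,
                               total_clearance = 20, maxit = 25)
  expect_gte(nrow(scan$flags), 1)
  pair <- sort(c(scan$flags$param1[1], scan$flags$param2[1]))
  expect_identical(pair, c("kliv_out", "kliv_p"))
  expect_lt(scan$flags$correlation[1], -0.9)  # only the sum is fixed
})

test_that("free total clearance with late-only data flags the plasma exits", {
  edges <- data.frame(
    source = c("plasma", "plasma", "organ_a", "organ_b"),
    target = c("organ_a", "organ_b", EXTERNAL, EXTERNAL),
    param = c("kp_a", "kp_b", "ka_out", "kb_out"))
  topo <- toy_topology(edges, c("plasma", "organ_a", "organ_b"))
  truth <- c(kp_a = 12, kp_b = 8, ka_out = 0.2, kb_out = 0.1)
  ds <- toy_dataset(topo, truth, times = c(0.5, 2, 7, 14, 28),
                    organs = c("plasma", "organ_a", "organ_b"))
  scan <- identifiability_scan(ds, topo, n_starts = 12, seed = 9,
                               total_clearance = NULL, maxit = 30)
  # with no early-time resolution only the ratio of the plasma exits is
  # identified; their common scale drifts across starts
  expect_true(any(
    (scan$flags$param1 == "kp_a" & scan$flags$param2 == "kp_b") |
      (scan$flags$param1 == "kp_b" & scan$flags$param2 == "kp_a")))
})

test_that("single-route exits with informative data are not flagged", {
  edges <- data.frame(
    source = c("plasma", "plasma", "organ_a", "organ_b"),
    target = c("organ_a", "organ_b", "plasma", "plasma"),
    param = c("kp_a", "kp_b", "ka_p", "kb_p"))
  topo <- toy_topology(edges, c("plasma", "organ_a", "organ_b"))
  truth <- c(kp_a = 12, kp_b = 8, ka_p = 0.3, kb_p = 0.1)
  ds <- toy_dataset(topo, truth,
                    times = c(0.5, 1, 2, 4, 7, 14, 21, 28),
                    organs = c("plasma", "organ_a", "organ_b"),
                    sd_plasma = 0.5)
  scan <- identifiability_scan(ds, topo, n_starts = 10, seed = 2,
                               total_clearance = 20, maxit = 30)
  expect_identical(nrow(scan$flags), 0L)
  expect_true(all(scan$spread < 0.25))
})

test_that("scan output is structured and seeded", {
  edges <- data.frame(
    source = c("plasma", "organ_a"),
    target = c("organ_a", "plasma"),
    param = c("kp_a", "ka_p"))
  topo <- toy_topology(edges, c("plasma", "organ_a"))
  truth <- c(kp_a = 5, ka_p = 0.2)
  ds <- toy_dataset(topo, truth, times = c(0.5, 2, 7, 21),
                    organs = c("plasma", "organ_a"))
  s1 <- identifiability_scan(ds, topo, n_starts = 5, seed = 7,
                             total_clearance = 5, maxit = 40)
  s2 <- identifiability_scan(ds, topo, n_starts = 5, seed = 7,
                             total_clearance = 5, maxit = 40)
  expect_identical(s1$estimates, s2$estimates)
  expect_length(s1$fval, 5)
  expect_true(all(s1$accepted %in% c(TRUE, FALSE)))
})
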