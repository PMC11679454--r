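vocab <- foo_vocabulary()

test_that("mapping produces seven observation-scoped triples per record", {
  g1 <- map_observations_to_graph(tiny_obs()[1, ], vocab)
  obs_iri <- paste0(vocab$foo_ns, "observation_1")
  expect_identical(sum(g1$subject == obs_iri), 7L)
  # scaffold only for the empty table
  g0 <- map_observations_to_graph(tiny_obs()[0, ], vocab)
  expect_false(any(grepl("observation_", g0$subject)))
  # one node per record at scale
  obs <- simulate_trajectory(trajectory_config(n_obs = 300, seed = 6))
  g <- map_observations_to_graph(obs, vocab)
  expect_identical(count_observation_nodes(g, vocab), 300L)
  expect_error(map_observations_to_graph(rbind(tiny_obs(), tiny_obs()), vocab),
               "duplicate obs_id")
})

test_that("plantation node carries three triples and replace semantics", {
  g <- map_observations_to_graph(tiny_obs(), vocab)
  n0 <- nrow(g)
  g <- add_plantation(g, 5.25, 118.70, vocab)
  expect_identical(nrow(g), n0 + 3L)
  expect_error(add_plantation(g, 5.30, 118.80, vocab), "replace")
  g2 <- add_plantation(g, 5.30, 118.80, vocab, replace = TRUE)
  expect_identical(nrow(g2), nrow(g))
  plat <- g2$object[g2$subject == vocab$plantation_node &
                      g2$predicate == vocab$p_lat]
  expect_identical(as.numeric(plat), 5.30)
})

test_that("extraction reproduces the source rows bit-exactly, ordered by time", {
  obs <- simulate_trajectory(trajectory_config(n_obs = 150, seed = 8))
  g <- map_observations_to_graph(obs, vocab)
  rows <- select_observations(g, vocab)
  expect_identical(nrow(rows), 150L)
  expect_identical(rows$latitude, obs$latitude)
  expect_identical(rows$longitude, obs$longitude)
  expect_identical(rows$local_date, as.character(obs$local_date))
  expect_identical(rows$local_time, obs$local_time)
  expect_identical(nrow(select_observations(triple_graph(), vocab)), 0L)
})

test_that("observations missing a property are skipped with a count", {
  g <- map_observations_to_graph(tiny_obs(), vocab)
  g <- g[!(g$predicate == vocab$p_time &
             g$subject == paste0(vocab$foo_ns, "observation_2")), ]
  expect_warning(rows <- select_observations(g, vocab), "1 observation")
  expect_identical(nrow(rows), 2L)
})

test_that("the poaching rule matches the buffer-membership oracle exactly", {
  set.seed(33)
  n <- 500L
  obs <- tibble::tibble(
    obs_id = seq_len(n),
    local_date = as.Date("2015-01-01") + (seq_len(n) - 1) %/% 12,
    local_time = sprintf("%02d:00:00", ((seq_len(n) - 1) %% 12) * 2),
    latitude = runif(n, 5.0, 5.4),
    longitude = runif(n, 118.4, 119.0)
  )
  g <- map_observations_to_graph(obs, vocab)
  g <- add_plantation(g, 5.2, 118.66, vocab)
  g2 <- apply_poaching_rule(g, vocab, radius_km = 5)
  expect_identical(attr(g2, "n_annotated"), n)
  flags <- g2[g2$predicate == vocab$p_poaching, c("subject", "object")]
  want <- within_buffer(obs$latitude, obs$longitude, 5.2, 118.66, 5)
  names(want) <- paste0(vocab$foo_ns, "observation_", obs$obs_id)
  expect_identical(as.integer(flags$object[match(names(want), flags$subject)]),
                   unname(want))
  expect_identical(flags$object[flags$subject ==
    paste0(vocab$foo_ns, "observation_",
           obs$obs_id[which.min(haversine_km(obs$latitude, obs$longitude,
                                             5.2, 118.66))])][1],
    as.character(want[which.min(haversine_km(obs$latitude, obs$longitude,
                                             5.2, 118.66))]))
})

test_that("rule application is conservative and idempotent", {
  obs <- tiny_obs()
  g <- add_plantation(map_observations_to_graph(obs, vocab), 5.2, 118.66, vocab)
  g1 <- apply_poaching_rule(g, vocab)
  expect_identical(nrow(g1), nrow(g) + nrow(obs))  # one new triple per obs
  expect_true(all(g$subject %in% g1$subject))      # nothing removed
  g2 <- apply_poaching_rule(g1, vocab)
  expect_true(graph_equal(g1, g2))
  # with a different radius the flags are replaced, not duplicated
  g3 <- apply_poaching_rule(g1, vocab, radius_km = 0.001)
  expect_identical(nrow(g3), nrow(g1))
})

test_that("a graph without a plantation node raises a rule error", {
  g <- map_observations_to_graph(tiny_obs(), vocab)
  expect_error(apply_poaching_rule(g, vocab), "plantation")
})

test_that("co-located observation is flagged 1; remote observations 0", {
  obs <- tiny_obs()
  obs$latitude <- c(5.25, 6.9, 7.2)
  obs$longitude <- c(118.70, 119.0, 119.0)
  g <- add_plantation(map_observations_to_graph(obs, vocab), 5.25, 118.70, vocab)
  g <- apply_poaching_rule(g, vocab)
  flags <- g[g$predicate == vocab$p_poaching, ]
  f <- setNames(flags$object, flags$subject)
  expect_identical(unname(f[paste0(vocab$foo_ns, "observation_1")]), "1")
  expect_identical(unname(f[paste0(vocab$foo_ns, "observation_2")]), "0")
  expect_identical(unname(f[paste0(vocab$foo_ns, "observation_3")]), "0")
})

test_that("inserted predictions become rule-covered observation nodes", {
  g <- add_plantation(map_observations_to_graph(tiny_obs(), vocab),
                      5.25, 118.70, vocab)
  preds <- tibble::tibble(latitude = c(5.253, 5.35), longitude = c(118.705, 118.9),
                          local_date = c("2019-01-01", "2019-01-01"),
                          local_time = c("00:00:00", "02:00:00"))
  g2 <- insert_predictions(g, preds, vocab)
  expect_identical(count_observation_nodes(g2, vocab), 5L)
  expect_true(graph_equal(insert_predictions(g, preds[0, ], vocab), g))
  g3 <- apply_poaching_rule(g2, vocab)
  pred1 <- paste0(vocab$foo_ns, "observation_pred_1")  # ~1 km from plantation
  flag <- g3$object[g3$subject == pred1 & g3$predicate == vocab$p_poaching]
  expect_identical(flag, "1")
  prov <- g3[g3$subject == pred1 & g3$predicate == vocab$p_predicted_by, ]
  expect_identical(nrow(prov), 1L)
})

test_that("the poaching report keeps five triples per flagged observation", {
  g <- add_plantation(map_observations_to_graph(tiny_obs(), vocab),
                      5.2, 118.66, vocab)
  expect_identical(nrow(construct_poaching_report(g, vocab)), 0L)
  g <- apply_poaching_rule(g, vocab)
  rep <- construct_poaching_report(g, vocab)
  expect_identical(nrow(rep), 15L)
  expect_false(vocab$p_time %in% rep$predicate)
  # report round-trips through Turtle unchanged
  path <- withr::local_tempfile(fileext = ".ttl")
  serialize_turtle(rep, path, vocab)
  expect_true(graph_equal(parse_turtle(path), rep))
})

test_that("end-to-end: simulate -> CSV -> graph -> extraction is lossless", {
  obs <- simulate_trajectory(trajectory_config(n_obs = 120, seed = 13))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_observations_csv(obs, csv)
  rows <- select_observations(
    map_observations_to_graph(read_observations_csv(csv), vocab), vocab)
  expect_identical(rows$latitude, obs$latitude)
  expect_identical(rows$longitude, obs$longitude)
})
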