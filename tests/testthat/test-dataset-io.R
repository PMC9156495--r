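test_that("the bundled default network is the 8-compartment serum-hub star", {
  net <- default_network()
  expect_length(net$compartments, 8L)
  expect_identical(nrow(net$axes), 7L)
  # Independent graph-construction check with igraph: connected, star-shaped.
  g <- igraph::graph_from_edgelist(net$axes, directed = FALSE)
  expect_true(igraph::is_connected(g))
  deg <- igraph::degree(g)
  expect_identical(unname(deg["serum"]), 7)
  expect_true(all(deg[setdiff(names(deg), "serum")] == 1))
})

test_that("network validation rejects malformed graphs", {
  expect_error(traffic_network(c("liver", "liver")), "unique")
  expect_error(traffic_network(c("liver", "serum"),
                               list(c("liver", "liver"))), "self-loop")
  expect_error(traffic_network(c("liver", "serum"),
                               list(c("liver", "kidney"))), "not declared")
  # two disconnected stars
  expect_error(traffic_network(c("a", "b", "c", "d"),
                               list(c("a", "b"), c("c", "d"))), "connected")
  expect_error(traffic_network(c("a", "b", "c"), list(c("a", "b"))),
               "connected")
})

test_that("network config files round-trip and bad ones fail", {
  net <- tiny_network()
  path <- withr::local_tempfile(fileext = ".txt")
  write_network(net, path)
  back <- read_network(path)
  expect_identical(back$compartments, net$compartments)
  expect_identical(back$axes, net$axes)

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("compartments:", "  - liver", "axes:", "  - [liver, liver]"), bad)
  expect_error(read_network(bad), "self-loop")
  writeLines(c("compartments:", "  - liver", "stray line"), bad)
  expect_error(read_network(bad), "cannot parse")
})

test_that("abundance_table validates records and reports row numbers", {
  net <- tiny_network()
  ok <- data.frame(sample_id = c("c1", "c2", "c3", "d1", "d2", "d3"),
                   phenotype = rep(c("ctrl", "case"), each = 3),
                   compartment = "liver",
                   lipid = "PC(34:1)",
                   signal = c(1, 2, 3, 4, 5, 6))
  tbl <- abundance_table(ok, net)
  expect_s3_class(tbl, "abundance_table")
  expect_identical(nrow(tbl), 6L)
  expect_identical(attr(tbl, "phenotypes"), c("case", "ctrl"))

  three <- rbind(ok, data.frame(sample_id = "x1", phenotype = "extra",
                                compartment = "liver", lipid = "PC(34:1)",
                                signal = 1))
  expect_error(abundance_table(three, net), "case, ctrl, extra")

  neg <- ok; neg$signal[4] <- -1
  expect_error(abundance_table(neg, net), "row\\(s\\) 4")

  dup <- rbind(ok, ok[2, ])
  expect_error(abundance_table(dup, net), "duplicate")

  bad_comp <- ok; bad_comp$compartment[2] <- "kidney"
  expect_error(abundance_table(bad_comp, net), "kidney")

  swapped <- rbind(ok, data.frame(sample_id = "c2", phenotype = "case",
                                  compartment = "serum", lipid = "PC(34:1)",
                                  signal = 1))  # sample in both groups
  expect_error(abundance_table(swapped, net), "both phenotypes")

  expect_error(abundance_table(ok[, -5], net), "missing column")
})

test_that("read/write round-trip is lossless for both delimiters", {
  sim <- simulate_lta(simulation_design(network = tiny_network(),
                                        lipid_panel = c("PC(34:1)", "TG(50:1)"),
                                        n_per_group = 3L, seed = 11L))
  for (ext in c(".csv", ".tsv")) {
    path <- withr::local_tempfile(fileext = ext)
    write_abundance_table(sim$table, path)
    back <- read_abundance_table(path, tiny_network())
    expect_equal(as.data.frame(back), as.data.frame(sim$table))
  }
})

test_that("empty or missing abundance files are rejected by name", {
  path <- withr::local_tempfile(fileext = ".csv")
  file.create(path)
  expect_error(read_abundance_table(path, tiny_network()), "empty")
  expect_error(read_abundance_table("no/such/file.csv", tiny_network()),
               "not found")
})

test_that("summarise_groups: species summaries, zeros for absent records", {
  net <- tiny_network()
  tbl <- make_table(list(
    ctrl = list(liver = list("PC(34:1)" = c(2, 4))),
    case = list(liver = list("PC(34:1)" = c(3, 5)))))
  s <- summarise_groups(tbl, "species")
  ctrl <- s[s$unit == "PC(34:1)" & s$phenotype == "ctrl", ]
  expect_equal(ctrl$mean, 3)
  expect_equal(ctrl$sd, sqrt(2))
  expect_identical(ctrl$n, 2L)
  expect_false(ctrl$degenerate)

  # a sample missing a species record contributes 0 to that species
  rec <- data.frame(sample_id = c("c1", "c2", "c2"),
                    phenotype = "ctrl", compartment = "liver",
                    lipid = c("TG(44:0)", "TG(44:0)", "TG(46:0)"),
                    signal = c(1, 1, 2))
  rec <- rbind(rec, data.frame(sample_id = "d1", phenotype = "case",
                               compartment = "liver", lipid = "TG(44:0)",
                               signal = 1))
  tbl2 <- abundance_table(rec, net)
  s2 <- summarise_groups(tbl2, "species")
  tg460 <- s2[s2$unit == "TG(46:0)" & s2$phenotype == "ctrl", ]
  expect_equal(tg460$mean, 1)       # (0 + 2) / 2
  expect_equal(tg460$sd, sqrt(2))
  one <- s2[s2$phenotype == "case" & s2$unit == "TG(44:0)", ]
  expect_true(one$degenerate)
  expect_equal(one$sd, 0)
})

test_that("class values are per-sample sums; class summary equals aggregated species", {
  net <- tiny_network()
  tbl <- make_table(list(
    ctrl = list(liver = list("TG(44:0)" = c(1, 2), "TG(46:0)" = c(2, 3),
                             "PC(34:1)" = c(5, 5))),
    case = list(liver = list("TG(44:0)" = c(4, 6), "TG(46:0)" = c(1, 1),
                             "PC(34:1)" = c(5, 7)))))
  cl <- summarise_groups(tbl, "class")
  tg_ctrl <- cl[cl$unit == "TG" & cl$phenotype == "ctrl", ]
  expect_equal(tg_ctrl$mean, mean(c(1 + 2, 2 + 3)))  # sum within sample first
  expect_equal(tg_ctrl$sd, sd(c(3, 5)))

  # property: class summary == species signals aggregated per sample, any data
  sim <- simulate_lta(simulation_design(network = tiny_network(),
                                        n_per_group = 4L, seed = 3L,
                                        detection_dropout = 0.2))
  cl2 <- summarise_groups(sim$table, "class")
  dt <- as.data.frame(sim$table)
  panel <- attr(sim$table, "panel")
  dt$head <- panel$head_group[match(dt$lipid, panel$name)]
  agg <- aggregate(signal ~ head + phenotype + compartment + sample_id,
                   dt, sum)
  for (i in sample(nrow(cl2), 20)) {
    r <- cl2[i, ]
    vals <- agg$signal[agg$head == r$unit & agg$phenotype == r$phenotype &
                       agg$compartment == r$compartment]
    # absent species contribute 0; every sample has some record here
    expect_equal(r$mean, mean(vals), tolerance = 1e-12)
  }
})
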