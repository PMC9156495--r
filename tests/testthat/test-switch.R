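# Brute-force truth table for one lipid at one scope: presence (p1, p2) for
# the two phenotypes maps to A / B(attributed) / absent.
expected_type <- function(p1, p2, phen) {
  if (p1 && p2) list(type = "A", phenotype = NA_character_)
  else if (p1) list(type = "B", phenotype = phen[1])
  else if (p2) list(type = "B", phenotype = phen[2])
  else NULL
}

test_that("node classification enumerates the A/B truth table", {
  net <- tiny_network()
  phen <- c("case", "ctrl")  # sorted label order used by the package
  for (p_ctrl in c(TRUE, FALSE)) {
    for (p_case in c(TRUE, FALSE)) {
      at <- do.call(rbind, c(
        if (p_ctrl) list(data.frame(phenotype = "ctrl", compartment = "liver",
                                    lipid = "PC(34:1)")),
        if (p_case) list(data.frame(phenotype = "case", compartment = "liver",
                                    lipid = "PC(34:1)")),
        # anchor both phenotypes so the table always has two groups
        list(data.frame(phenotype = c("ctrl", "case"), compartment = "serum",
                        lipid = "TG(50:1)"))))
      pm <- call_presence(presence_table(at, net,
                                         lipids = c("PC(34:1)", "TG(50:1)")))
      cls <- classify_node(pm, "liver")
      row <- cls[cls$lipid == "PC(34:1)", ]
      exp <- expected_type(p_case, p_ctrl, phen)
      if (is.null(exp)) {
        expect_identical(nrow(row), 0L)  # present in neither: omitted
      } else {
        expect_identical(row$type, exp$type)
        expect_identical(row$phenotype, exp$phenotype)
      }
    }
  }
  expect_error(classify_node(pm, "kidney"), "unknown compartment")
})

test_that("axis classification: brute force over all presence combinations", {
  net <- tiny_network()
  phen <- c("case", "ctrl")
  combos <- expand.grid(ctrl_liver = c(TRUE, FALSE), ctrl_serum = c(TRUE, FALSE),
                        case_liver = c(TRUE, FALSE), case_serum = c(TRUE, FALSE))
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    at <- do.call(rbind, c(
      if (cb$ctrl_liver) list(data.frame(phenotype = "ctrl", compartment = "liver", lipid = "PC(34:1)")),
      if (cb$ctrl_serum) list(data.frame(phenotype = "ctrl", compartment = "serum", lipid = "PC(34:1)")),
      if (cb$case_liver) list(data.frame(phenotype = "case", compartment = "liver", lipid = "PC(34:1)")),
      if (cb$case_serum) list(data.frame(phenotype = "case", compartment = "serum", lipid = "PC(34:1)")),
      list(data.frame(phenotype = c("ctrl", "case"), compartment = "brain", lipid = "TG(50:1)"))))
    pm <- call_presence(presence_table(at, net, lipids = c("PC(34:1)", "TG(50:1)")))
    cls <- classify_axis(pm, c("serum", "liver"))
    row <- cls[cls$lipid == "PC(34:1)", ]
    exp <- expected_type(cb$case_liver && cb$case_serum,
                         cb$ctrl_liver && cb$ctrl_serum, phen)
    if (is.null(exp)) expect_identical(nrow(row), 0L)
    else {
      expect_identical(row$type, exp$type)
      expect_identical(row$phenotype, exp$phenotype)
    }
  }
})

test_that("a planted control-only lipid is exactly the axis B-list", {
  net <- tiny_network()
  at <- rbind(
    expand.grid(phenotype = c("ctrl", "case"), compartment = net$compartments,
                lipid = "PC(34:1)", stringsAsFactors = FALSE),
    data.frame(phenotype = "ctrl", compartment = c("serum", "liver"),
               lipid = "TG(44:0)"))
  pm <- call_presence(presence_table(at, net, lipids = c("PC(34:1)", "TG(44:0)")))
  sw <- run_switch(pm, jparams = jaccard_params(200, seed = 4))
  expect_identical(b_type_lipids(sw, "serum-liver", "ctrl"), "TG(44:0)")
  expect_identical(b_type_lipids(sw, "serum-liver", "case"), character(0))
  expect_identical(b_type_lipids(sw, "serum-brain", "ctrl"), character(0))
})

test_that("find_ubiquitous attributes per phenotype, network-wide", {
  net <- tiny_network()
  everywhere <- expand.grid(phenotype = c("ctrl", "case"),
                            compartment = net$compartments,
                            lipid = "PC(34:1)", stringsAsFactors = FALSE)
  ctrl_only <- expand.grid(phenotype = "ctrl", compartment = net$compartments,
                           lipid = "PE(38:4)", stringsAsFactors = FALSE)
  gappy <- data.frame(phenotype = "case", compartment = c("serum", "liver"),
                      lipid = "PI(38:6)")
  pm <- call_presence(presence_table(rbind(everywhere, ctrl_only, gappy), net,
                                     lipids = c("PC(34:1)", "PE(38:4)", "PI(38:6)")))
  ub <- find_ubiquitous(pm)
  expect_setequal(paste(ub$lipid, ub$phenotype),
                  c("PC(34:1) ctrl", "PC(34:1) case", "PE(38:4) ctrl"))
  # U-type in both phenotypes implies A-type at every node scope
  for (comp in net$compartments) {
    cls <- classify_node(pm, comp)
    expect_identical(cls$type[cls$lipid == "PC(34:1)"], "A")
  }
})

test_that("partition invariant: |A| + |B| = lipids present in >= 1 phenotype", {
  set.seed(21)
  net <- tiny_network()
  lipids <- c("PC(34:1)", "PE(38:4)", "PI(38:6)", "TG(50:1)", "TG(58:11)")
  for (rep in 1:10) {
    grid <- expand.grid(phenotype = c("ctrl", "case"),
                        compartment = net$compartments, lipid = lipids,
                        stringsAsFactors = FALSE)
    at <- grid[runif(nrow(grid)) < 0.6, ]
    if (!all(c("ctrl", "case") %in% at$phenotype)) next
    pm <- call_presence(presence_table(at, net, lipids = lipids))
    sw <- run_switch(pm, jparams = jaccard_params(100, seed = rep))
    for (sc in unique(sw$jaccard$scope)) {
      kind <- sw$jaccard$scope_kind[sw$jaccard$scope == sc][1]
      cls <- sw$types[sw$types$scope == sc & sw$types$scope_kind == kind, ]
      if (kind == "node") {
        n_expected <- sum(sapply(lipids, function(l)
          any(at$lipid == l & at$compartment == sc)))
      } else {
        ends <- strsplit(sc, "-", fixed = TRUE)[[1]]
        n_expected <- sum(sapply(lipids, function(l)
          any(sapply(c("ctrl", "case"), function(g)
            all(sapply(ends, function(e)
              any(at$lipid == l & at$compartment == e & at$phenotype == g)))))))
      }
      expect_identical(nrow(cls), as.integer(n_expected))
      expect_identical(nrow(cls), sum(cls$type == "A") + sum(cls$type == "B"))
      expect_true(!anyDuplicated(cls$lipid))
    }
  }
})

test_that("relabelling phenotypes swaps B attributions, fixes A, U and J", {
  sim <- simulate_lta(paper_fixture(seed = 5L))
  tbl1 <- as.data.frame(sim$table)
  tbl2 <- tbl1
  tbl2$phenotype <- ifelse(tbl2$phenotype == "control", "diabetic", "control")
  net <- default_network()
  pm1 <- call_presence(abundance_table(tbl1, net, warn_unknown_head = FALSE))
  pm2 <- call_presence(abundance_table(tbl2, net, warn_unknown_head = FALSE))
  sw1 <- run_switch(pm1, jparams = jaccard_params(300, seed = 8))
  sw2 <- run_switch(pm2, jparams = jaccard_params(300, seed = 8))
  a1 <- sw1$types[sw1$types$type == "A", c("scope", "lipid")]
  a2 <- sw2$types[sw2$types$type == "A", c("scope", "lipid")]
  expect_equal(as.data.frame(a1), as.data.frame(a2))
  b1 <- sw1$types[sw1$types$type == "B", ]
  b2 <- sw2$types[sw2$types$type == "B", ]
  expect_identical(paste(b1$scope, b1$lipid), paste(b2$scope, b2$lipid))
  expect_identical(b1$phenotype,
                   ifelse(b2$phenotype == "control", "diabetic", "control"))
  expect_equal(sw1$jaccard$J, sw2$jaccard$J)
  u1 <- sw1$ubiquitous; u2 <- sw2$ubiquitous
  expect_setequal(paste(u1$lipid, u1$phenotype),
                  paste(u2$lipid, ifelse(u2$phenotype == "control",
                                         "diabetic", "control")))
})

test_that("single-compartment network: node lists populated, no axes", {
  net1 <- traffic_network("liver")
  tbl <- make_table(list(ctrl = list(liver = list("PC(34:1)" = c(1, 1))),
                         case = list(liver = list("PC(34:1)" = c(1, 1)))),
                    network = net1)
  sw <- run_switch(call_presence(tbl), jparams = jaccard_params(100, seed = 1))
  expect_identical(unique(sw$types$scope_kind), "node")
  expect_identical(sw$types$type, "A")
  expect_identical(nrow(sw$jaccard), 1L)
})

test_that("identical phenotypes give all-A scopes with J = 1", {
  net <- tiny_network()
  at <- expand.grid(phenotype = c("ctrl", "case"),
                    compartment = c("serum", "liver"),
                    lipid = c("PC(34:1)", "TG(50:1)"), stringsAsFactors = FALSE)
  pm <- call_presence(presence_table(at, net, lipids = c("PC(34:1)", "TG(50:1)")))
  sw <- run_switch(pm, jparams = jaccard_params(100, seed = 6))
  expect_true(all(sw$types$type == "A"))
  expect_true(all(sw$jaccard$J == 1))
})

test_that("axis lists never exceed the endpoint node lists per phenotype", {
  sim <- simulate_lta(paper_fixture(seed = 2L))
  pm <- call_presence(sim$table)
  sw <- run_switch(pm, jparams = jaccard_params(100, seed = 2))
  net <- default_network()
  tt <- as.data.frame(sw$types)
  for (i in seq_len(nrow(net$axes))) {
    ax <- axis_label <- paste(net$axes[i, ], collapse = "-")
    for (g in c("control", "diabetic")) {
      on_axis <- tt$lipid[tt$scope == ax &
                          (tt$type == "A" | (!is.na(tt$phenotype) & tt$phenotype == g))]
      for (end in net$axes[i, ]) {
        at_node <- tt$lipid[tt$scope == end &
                            (tt$type == "A" | (!is.na(tt$phenotype) & tt$phenotype == g))]
        expect_true(all(on_axis %in% at_node))
      }
    }
  }
})
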