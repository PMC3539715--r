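# Constrained-parsimony dating, census, rates and validation tests.

test_that("gene origins match the spec'd placements", {
  pm <- presence_from_list(list(
    g_human = "human",
    g_hc    = c("human", "chimpanzee"),
    g_prim  = c("human", "macaque"),
    g_eua   = c("human", "mouse"),
    g_root  = c("human", "cow"),
    g_all   = np_species()))
  expect_equal(gene_origin_branch("g_human", pm), "human")
  expect_equal(gene_origin_branch("g_hc", pm), "human-chimp")
  expect_equal(gene_origin_branch("g_prim", pm), "primates")
  expect_equal(gene_origin_branch("g_eua", pm), "euarchontoglires")
  expect_equal(gene_origin_branch("g_root", pm), "root")
  expect_equal(gene_origin_branch("g_all", pm), "root")
  expect_error(gene_origins(pm, "nope"), "unknown gene")
})

test_that("pair origin is the younger of the two gene origins", {
  pm <- presence_from_list(list(
    g_root = c("human", "cow"),
    g_prim = c("human", "macaque"),
    g_eua  = c("human", "rat"),
    g_hum  = "human"))
  expect_equal(ppi_origin_branch(c("g_root", "g_prim"), pm), "primates")
  expect_equal(ppi_origin_branch(c("g_root", "g_root"), pm), "root")
  expect_equal(ppi_origin_branch(c("g_hum", "g_eua"), pm), "human")
  expect_equal(ppi_origin_branch(c("g_eua", "g_root"), pm),
               oracle_pair_origin("euarchontoglires", "root"))
})

test_that("origin placement agrees with the brute-force scenario oracle", {
  pm <- random_presence(250, seed = 42)
  got <- gene_origins(pm)
  for (g in rownames(pm)) {
    present <- np_species()[pm[g, ] == 1L]
    expect_equal(unname(got[[g]]), oracle_gene_origin(present), info = g)
  }
})

test_that("origin census conserves pairs and is monotone toward human", {
  phy <- tiny_phylo()
  pm <- random_presence(80, seed = 3)
  set.seed(4)
  genes <- rownames(pm)
  net <- ppi_network(sample(genes, 150, TRUE), sample(genes, 150, TRUE),
                     quiet = TRUE)
  cen <- origin_census(net, pm, phy)
  expect_equal(sum(cen$counts), n_edges(net))
  expect_true(all(diff(cen$fractions) >= 0))
  expect_equal(unname(cen$fractions[["human"]]), 1)

  # all genes in all species -> everything at the root
  pm_all <- presence_from_list(setNames(
    replicate(10, np_species(), simplify = FALSE), sprintf("h%02d", 1:10)))
  net_all <- ppi_network(sprintf("h%02d", 1:9), sprintf("h%02d", 2:10),
                         quiet = TRUE)
  cen_all <- origin_census(net_all, pm_all, phy)
  expect_equal(unname(cen_all$counts[["root"]]), 9L)
  expect_equal(unname(cen_all$fractions[["root"]]), 1)

  # a single primate-only pair: zero presence at the root
  pm_p <- presence_from_list(list(p1 = c("human", "macaque"),
                                  p2 = c("human", "chimpanzee", "macaque")))
  cen_p <- origin_census(ppi_network("p1", "p2"), pm_p, phy)
  expect_equal(unname(cen_p$counts[["primates"]]), 1L)
  expect_equal(unname(cen_p$fractions[["root"]]), 0)
})

test_that("with zero loss the inferred census equals the planted census", {
  cfg <- np_sim_config(n_genes = 400L, loss_rate = 0)
  phy <- simulate_phylogeny(cfg)
  org <- simulate_gene_origins(cfg, seed = 5)
  net <- simulate_network(cfg, org, seed = 6)
  pres <- simulate_presence(phy, org, 0, seed = 7)
  expect_identical(unname(gene_origins(pres$presence)[names(org)]),
                   unname(org))
  cen <- origin_census(net, pres$presence, phy)
  planted <- .mapply(function(a, b) {
    oracle_pair_origin(org[[a]], org[[b]])
  }, net$edges[c("a", "b")], NULL)
  expect_equal(unname(cen$counts),
               unname(vapply(np_branches("origin"), function(cl)
                 sum(unlist(planted) == cl), integer(1))))
})

test_that("concerted presence test flags planted correlated loss", {
  expect_error(concerted_presence_test(ppi_network("a", "b"),
                                       random_presence(2, 1), n_null = 0),
               "n_null")
  # plant concordance: partners share their full presence pattern
  set.seed(8)
  n <- 120
  genes <- sprintf("c%03d", seq_len(2 * n))
  a <- genes[seq_len(n) * 2 - 1]; b <- genes[seq_len(n) * 2]
  others <- setdiff(np_species(), "human")
  spec <- list()
  for (i in seq_len(n)) {
    sp <- c("human", sample(others, sample(2:6, 1)))
    spec[[a[i]]] <- sp; spec[[b[i]]] <- sp
  }
  pm <- presence_from_list(spec)
  ct <- concerted_presence_test(ppi_network(a, b), pm, n_null = 99,
                                seed = 10)
  expect_lte(ct$pooled$p_empirical, 0.01)
  expect_equal(sum(ct$status_counts[, c("2", "1")]), 0)
})

test_that("concerted presence p-values are calibrated under independence", {
  set.seed(12)
  ps <- vapply(1:60, function(i) {
    pm <- random_presence(60, seed = 1000 + i)
    genes <- rownames(pm)
    net <- ppi_network(sample(genes, 90, TRUE), sample(genes, 90, TRUE),
                       quiet = TRUE)
    concerted_presence_test(net, pm, n_null = 49,
                            seed = 5000 + 100 * i)$pooled$p_empirical
  }, numeric(1))
  # under the null the empirical p is near-uniform on {1/50, ..., 1}
  expect_gt(mean(ps <= 0.5), 0.3)
  expect_lt(mean(ps <= 0.5), 0.7)
})

test_that("loss and gain rates follow their defining arithmetic", {
  phy <- tiny_phylo()
  # 10 exposed pairs on the horse-dog stem, 2 events (one member absent
  # from both horse and dog), Ks 0.09
  spec <- list()
  for (i in 1:20) spec[[sprintf("e%02d", i)]] <- c("human", "horse", "dog")
  spec$e01 <- c("human", "cow")     # lost on the stem, still exposed
  spec$e03 <- c("human", "cow")
  pm <- presence_from_list(spec)
  net <- ppi_network(sprintf("e%02d", seq(1, 20, 2)),
                     sprintf("e%02d", seq(2, 20, 2)), quiet = TRUE)
  lr <- loss_rate("horse-dog", net, pm, phy)
  expect_equal(lr$exposure, 10L)
  expect_equal(lr$events, 2L)
  expect_equal(lr$rate, 2 / 10 / 0.09)
  # zero events -> rate 0
  spec$e01 <- c("human", "horse", "dog"); spec$e03 <- spec$e01
  lr0 <- loss_rate("horse-dog", net, presence_from_list(spec), phy)
  expect_equal(lr0$rate, 0)

  cen <- structure(list(counts = c(root = 95L, euarchontoglires = 0L,
                                   primates = 5L, `human-chimp` = 0L,
                                   human = 0L),
                        fractions = c(root = .95, euarchontoglires = .95,
                                      primates = 1, `human-chimp` = 1,
                                      human = 1),
                        n_pairs = 100L), class = "origin_census")
  phy2 <- tiny_phylo(replace(tiny_ks, "primates", 0.25))
  gr <- gain_rate("primates", cen, phy2)
  expect_equal(gr$exposure, 100L)
  expect_equal(gr$rate, 5 / 100 / 0.25)
  expect_equal(gain_rate("human", cen, phy2)$rate, 0)
})

test_that("rates are invariant to gene relabelling", {
  phy <- tiny_phylo()
  pm <- random_presence(60, seed = 21)
  set.seed(22)
  genes <- rownames(pm)
  net <- ppi_network(sample(genes, 100, TRUE), sample(genes, 100, TRUE),
                     quiet = TRUE)
  relabel <- setNames(sprintf("zz%04d", seq_along(genes)), genes)
  pm2 <- pm; rownames(pm2) <- unname(relabel[rownames(pm)])
  net2 <- ppi_network(relabel[net$edges$a], relabel[net$edges$b],
                      quiet = TRUE)
  for (br in np_branches("loss")) {
    expect_equal(loss_rate(br, net2, pm2, phy)$rate,
                 loss_rate(br, net, pm, phy)$rate)
  }
  c1 <- origin_census(net, pm, phy); c2 <- origin_census(net2, pm2, phy)
  expect_equal(gain_rate("primates", c2, phy)$rate,
               gain_rate("primates", c1, phy)$rate)
})

test_that("steady-state correction discounts the raw root fraction", {
  phy <- tiny_phylo()
  pm <- random_presence(50, seed = 31)
  set.seed(32)
  genes <- rownames(pm)
  net <- ppi_network(sample(genes, 80, TRUE), sample(genes, 80, TRUE),
                     quiet = TRUE)
  cen <- origin_census(net, pm, phy)
  ss0 <- steady_state_correction(0, cen, phy)
  expect_identical(ss0$corrected, ss0$raw)
  expect_identical(ss0$raw, unname(cen$fractions[["root"]]))

  g <- 0.2
  ss <- steady_state_correction(g, cen, phy)
  n_child <- cumsum(cen$counts)
  ks <- vapply(np_branches("origin"), function(b) phy$ks[[b]], numeric(1))
  discount <- max(0, 1 - sum(g * n_child * ks) / cen$n_pairs)
  expect_equal(ss$corrected, ss$raw * discount)
  expect_lt(ss$corrected, ss$raw)
  expect_error(steady_state_correction(-1, cen, phy), "nonnegative")
})

test_that("degree-age trend: identity on own edges, sign under coupling", {
  phy <- tiny_phylo()
  # power fixture: well-populated young classes, mild degree tail, strong
  # age coupling, so class mean degrees are stable at this scale
  cfg <- np_sim_config(n_genes = 600L, age_degree_coupling = 3,
                       mean_degree = 6, degree_exponent = 3.5,
                       origin_probs = c(root = 0.8,
                                        euarchontoglires = 0.05,
                                        primates = 0.05,
                                        `human-chimp` = 0.05,
                                        human = 0.05),
                       loss_rate = 0)
  org <- simulate_gene_origins(cfg, seed = 41)
  net <- simulate_network(cfg, org, seed = 42)
  pres <- simulate_presence(phy, org, 0, seed = 43)
  da <- degree_age_correlation(net, pres$presence, phy, n_null = 99,
                               seed = 44)
  # old-coupled hubs: mean degree increases with branch age
  expect_gt(da$test$observed, 0)
  expect_lte(da$test$p_empirical, 0.05)
  # the analysis run on the network's own edge list reproduces observed r
  stat <- netpaleo:::.np_degree_age_stat(net$edges$a, net$edges$b,
                                         pres$presence, phy)
  expect_identical(stat$r, da$test$observed)
})
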