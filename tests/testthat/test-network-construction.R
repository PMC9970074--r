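# Network assembly: CI pruning, strength definitions, population/physician
# consistency, layout, and lossless export/import.

test_that("pruning follows the equal-tailed interval exactly", {
  # degenerate draws at +0.3: interval [0.3, 0.3] excludes zero
  pr <- prune_edges(rep(0.3, 600))
  expect_true(pr$retain)
  expect_equal(pr$ci_low, 0.3)
  expect_equal(pr$ci_high, 0.3)
  # symmetric draws straddle zero
  set.seed(1)
  expect_false(prune_edges(rnorm(2000))$retain)
  # constructed sample whose empirical 2.5%/97.5% quantiles bracket zero
  set.seed(2)
  d <- rnorm(1000, 0.19, 0.1)
  q <- quantile(d, c(0.025, 0.975), names = FALSE)
  expect_lt(q[1], 0); expect_gt(q[2], 0)
  pr2 <- prune_edges(d)
  expect_false(pr2$retain)
  expect_equal(pr2$ci_low, q[1])
  expect_equal(pr2$ci_high, q[2])
  expect_error(prune_edges(d, level = 1), "level")
})

test_that("pruning is monotone across credible levels on every fitted edge", {
  net95 <- fix_population()
  net99 <- build_population_network(fix_fits(), fix_ratings(), level = 0.99)
  # every edge pruned at 0.95 is also pruned at 0.99
  expect_true(all(net99$retain[!net95$retain] == FALSE))
  expect_true(all(which(net99$retain) %in% which(net95$retain)))
  # the same holds per physician
  nets99 <- build_physician_network(fix_fits(), fix_ratings(), "P01", level = 0.99)
  nets95 <- fix_networks()[["P01"]]
  expect_true(all(which(nets99$retain) %in% which(nets95$retain)))
})

test_that("strengths equal brute-force sums over retained edges only", {
  for (net in c(fix_networks()[c("P01", "P07")], list(fix_population()))) {
    Wr <- net$W * net$retain
    expect_identical(unname(net$instrength), unname(colSums(Wr)))
    expect_identical(unname(net$outstrength), unname(rowSums(Wr)))
    expect_identical(unname(net$instrength_raw), unname(colSums(net$W)))
    expect_identical(unname(net$outstrength_raw), unname(rowSums(net$W)))
    expect_true(all(diag(net$W) == 0))
  }
})

test_that("removing one retained edge changes exactly the two incident strengths", {
  net <- fix_networks()[["P02"]]
  idx <- which(net$retain, arr.ind = TRUE)
  expect_gt(nrow(idx), 0)
  k <- idx[1, 1]; j <- idx[1, 2]
  w <- net$W[k, j]
  retain2 <- net$retain
  retain2[k, j] <- FALSE
  Wr2 <- net$W * retain2
  expect_equal(colSums(Wr2)[j], net$instrength[j] - w)
  expect_equal(rowSums(Wr2)[k], net$outstrength[k] - w)
  expect_equal(colSums(Wr2)[-j], net$instrength[-j])
  expect_equal(rowSums(Wr2)[-k], net$outstrength[-k])
})

test_that("activation is the physician's mean rating and stays on the 0-5 scale", {
  m <- sample_true_model(n_physicians = 3, seed = 41)
  r <- simulate_ratings(m, consultations = 15, discretize = TRUE, seed = 42)
  fits <- fit_all_nodes(r, mcmc = light_mcmc(43), varying = "independent")
  net <- build_physician_network(fits, r, "P02")
  R <- as.matrix(r[r$physician_id == "P02", paste0("skill_", 1:9)])
  expect_equal(unname(net$activation), unname(colMeans(R)))
  expect_true(all(net$activation >= 0 & net$activation <= 5))
  # population activation averages physician activations with equal weight
  pop <- build_population_network(fits, r)
  acts <- sapply(c("P01", "P02", "P03"), function(id) {
    colMeans(as.matrix(r[r$physician_id == id, paste0("skill_", 1:9)]))
  })
  expect_equal(unname(pop$activation), unname(rowMeans(acts)))
})

test_that("mean physician edge weights track the population weights on balanced data", {
  nets <- fix_networks()
  pop <- fix_population()
  Wbar <- Reduce(`+`, lapply(nets, `[[`, "W")) / length(nets)
  off <- row(Wbar) != col(Wbar)
  expect_lt(max(abs(Wbar[off] - pop$W[off])), 0.1)
  expect_gt(cor(Wbar[off], pop$W[off]), 0.95)
})

test_that("edge weights correlate with the analytic truth across physicians", {
  dense <- fix_dense_networks()
  nets <- dense$networks
  truth <- true_network_params(dense$model)
  est <- c(); tru <- c()
  for (id in names(nets)) {
    W <- nets[[id]]$W
    TW <- truth$edges[id, , ]
    keep <- nets[[id]]$retain
    est <- c(est, W[keep]); tru <- c(tru, TW[keep])
  }
  expect_gt(length(est), 10)
  expect_gte(cor(est, tru), 0.8)
})

test_that("Fruchterman-Reingold layout is deterministic and distance tracks weight", {
  net <- layout_network(fix_population(), seed = 99)
  net2 <- layout_network(fix_population(), seed = 99)
  expect_identical(net$layout, net2$layout)
  expect_true(all(is.finite(net$layout)))
  expect_equal(dim(net$layout), c(9, 2))
  net3 <- layout_network(fix_population(), seed = 100)
  expect_false(identical(net$layout, net3$layout))

  # two 4-cliques joined by one weak edge: within-clique distances smaller
  sk <- paste0("skill_", 1:9)
  W <- matrix(0, 9, 9, dimnames = list(sk, sk))
  for (a in 1:4) for (b in 1:4) if (a != b) W[a, b] <- 1
  for (a in 5:8) for (b in 5:8) if (a != b) W[a, b] <- 1
  W[4, 5] <- 0.05
  toy <- structure(list(
    physician_id = "toy", type = "physician", level = 0.95,
    skills = skill_labels(), W = W, retain = W != 0,
    ci_low = W, ci_high = W,
    activation = setNames(rep(3, 9), sk),
    instrength = colSums(W), outstrength = rowSums(W),
    instrength_raw = colSums(W), outstrength_raw = rowSums(W),
    layout = NULL
  ), class = "sdm_network")
  lay <- layout_network(toy, seed = 7)$layout
  dists <- as.matrix(dist(lay))
  within <- c(dists[1:4, 1:4][upper.tri(diag(4))],
              dists[5:8, 5:8][upper.tri(diag(4))])
  between <- as.vector(dists[1:4, 5:8])
  expect_lt(mean(within), mean(between))
})

test_that("JSON export round-trips every network field", {
  net <- layout_network(fix_networks()[["P03"]], seed = 5)
  path <- tempfile(fileext = ".json")
  export_network(net, path)
  net2 <- import_network(path)
  expect_equal(net2$W, net$W)
  expect_identical(net2$retain, net$retain)
  expect_equal(net2$ci_low, net$ci_low)
  expect_equal(net2$ci_high, net$ci_high)
  expect_equal(unname(net2$activation), unname(net$activation))
  expect_equal(unname(net2$instrength), unname(net$instrength))
  expect_equal(unname(net2$outstrength), unname(net$outstrength))
  expect_equal(unname(net2$layout), unname(net$layout))
  expect_equal(net2$skills, net$skills)
  expect_equal(net2$physician_id, net$physician_id)
})

test_that("GraphML export is schema-shaped and round-trips weights and masks", {
  net <- layout_network(fix_population(), seed = 5)
  path <- tempfile(fileext = ".graphml")
  export_network(net, path, format = "graphml")
  doc <- xml2::read_xml(path)
  expect_equal(xml2::xml_name(doc), "graphml")
  expect_match(xml2::xml_attr(doc, "xmlns"),
               "graphml.graphdrawing.org", fixed = TRUE)
  net2 <- import_network(path)
  expect_equal(unname(net2$W), unname(net$W))
  expect_identical(unname(net2$retain), unname(net$retain))
  expect_equal(unname(net2$activation), unname(net$activation), tolerance = 1e-12)
  expect_equal(unname(net2$instrength), unname(net$instrength))
})

test_that("CSV edge lists contain retained edges only, with CI columns", {
  net <- fix_networks()[["P01"]]
  path <- tempfile(fileext = ".csv")
  export_network(net, path, format = "csv")
  el <- read.csv(path)
  expect_setequal(names(el), c("source_skill", "target_skill", "weight",
                               "retained", "ci_low", "ci_high"))
  expect_equal(nrow(el), sum(net$retain))
  expect_true(all(el$retained))
  for (i in seq_len(nrow(el))) {
    expect_equal(el$weight[i], net$W[el$source_skill[i], el$target_skill[i]])
  }
})
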