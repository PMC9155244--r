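test_that("collinear profiles form edges with the right sign", {
  bm <- rbind(gA = c(1, 2, 3, 4), gB = c(2, 4, 6, 8), gC = c(4, 3, 2, 1),
              gD = c(5, 1, 4, 2))
  colnames(bm) <- c("L0", "L4", "L8", "N0")
  net <- correlationNetwork(bm)
  ed <- as.data.frame(networkEdges(net))
  ab <- ed[ed$gene_a == "gA" & ed$gene_b == "gB", ]
  expect_equal(ab$r, 1)
  expect_equal(ab$sign, "positive")
  ac <- ed[ed$gene_a == "gA" & ed$gene_b == "gC", ]
  expect_equal(ac$r, -1)
  expect_equal(ac$sign, "negative")
  ## degree sum = 2 x edge count
  expect_equal(sum(networkDegree(net)), 2 * nrow(ed))
})

test_that("edge set equals a brute-force all-pairs recomputation", {
  set.seed(23)
  bm <- matrix(runif(20 * 4), 20, 4,
               dimnames = list(sprintf("g%02d", 1:20), c("L0", "L4", "L8", "N0")))
  net <- correlationNetwork(bm, r_threshold = 0.9)
  ed <- as.data.frame(networkEdges(net))
  got <- sort(paste(ed$gene_a, ed$gene_b))
  ## independent double loop
  want <- character()
  for (i in 1:19) for (j in (i + 1):20) {
    r <- cor(bm[i, ], bm[j, ])
    if (r > 0.9 || r < -0.9) {
      want <- c(want, paste(rownames(bm)[i], rownames(bm)[j]))
    }
  }
  expect_setequal(got, sort(want))
})

test_that("zero-variance genes are excluded and small inputs rejected", {
  bm <- rbind(gA = c(1, 2, 3, 4), gB = c(7, 7, 7, 7))
  colnames(bm) <- c("L0", "L4", "L8", "N0")
  expect_warning(net <- correlationNetwork(bm), "zero-variance")
  expect_false("gB" %in% networkNodes(net)$gene_id)
  expect_error(correlationNetwork(bm, "missing"), "absent")
})

test_that("hub detection follows the strict degree-15 and top-20% rules", {
  ## star: centre adjacent to 16 leaves -> highlighted; leaves (degree 1) not
  genes <- c("hub", sprintf("leaf%02d", 1:16))
  edges <- S4Vectors::DataFrame(gene_a = "hub", gene_b = genes[-1],
                                r = 0.95, sign = "positive")
  deg <- table(factor(c(edges$gene_a, edges$gene_b), levels = genes))
  nodes <- S4Vectors::DataFrame(gene_id = genes, degree = as.integer(deg),
                                highlighted = FALSE, hub = FALSE)
  net <- new("CoexpressionNetwork", nodes = nodes, edges = edges,
             rThreshold = 0.9)
  net <- detectHubs(net, hub_degree_min = 15, hub_top_frac = 0.2)
  nd <- as.data.frame(networkNodes(net))
  expect_true(nd$highlighted[nd$gene_id == "hub"])
  expect_false(any(nd$highlighted[nd$gene_id != "hub"]))
  ## 17 nodes -> ceiling(0.2 * 17) = 4 hubs, hub ranked first
  expect_equal(sum(nd$hub), 4)
  expect_equal(nd$gene_id[1], "hub")

  ## 10 nodes -> exactly 2 hubs
  nodes10 <- S4Vectors::DataFrame(gene_id = sprintf("g%02d", 1:10),
                                  degree = 10:1, highlighted = FALSE,
                                  hub = FALSE)
  net10 <- new("CoexpressionNetwork", nodes = nodes10,
               edges = S4Vectors::DataFrame(gene_a = character(),
                                            gene_b = character(),
                                            r = numeric(), sign = character()),
               rThreshold = 0.9)
  expect_equal(sum(networkNodes(detectHubs(net10))$hub), 2)

  ## empty network -> no hubs
  net0 <- correlationNetwork(matrix(runif(4), 1, 4,
                                    dimnames = list("only", c("L0", "L4", "L8", "N0"))))
  expect_equal(sum(networkNodes(detectHubs(net0))$hub), 1)  # ceil(0.2*1)=1 of itself
  expect_equal(nrow(networkEdges(net0)), 0)
})

test_that("degree ties are broken lexicographically by gene id", {
  nodes <- S4Vectors::DataFrame(gene_id = c("zz", "aa", "mm"),
                                degree = c(3L, 3L, 3L),
                                highlighted = FALSE, hub = FALSE)
  net <- new("CoexpressionNetwork", nodes = nodes,
             edges = S4Vectors::DataFrame(gene_a = character(),
                                          gene_b = character(),
                                          r = numeric(), sign = character()),
             rThreshold = 0.9)
  nd <- networkNodes(detectHubs(net, hub_top_frac = 1 / 3))
  expect_equal(nd$gene_id, c("aa", "mm", "zz"))
  expect_equal(sum(nd$hub), 1)
  expect_true(nd$hub[nd$gene_id == "aa"])
})

test_that("trait correlation recovers exact linear coupling and degeneracies", {
  dsn <- pipelineDesign()
  bm <- matrix(c(1, 2, 3, 4), 1, 4, dimnames = list("gH", c("L0", "L4", "L8", "N0")))
  ## TG = 100 - 10 x TPM exactly -> r = -1
  trait <- data.frame(sample_id = dsn$sample_id,
                      tg_mg_dl = 100 - 10 * c(1, 2, 3, 4)[as.integer(dsn$group)])
  tc <- traitCorrelation(bm, trait, dsn)
  expect_equal(tc$r, -1)

  ## constant trait -> missing value with warning
  trait$tg_mg_dl <- 50
  expect_warning(tc2 <- traitCorrelation(bm, trait, dsn), "constant")
  expect_true(is.na(tc2$r))

  ## noiseless planted hub from simulateTrait -> |r| = 1 within 1e-12
  hub_tpm <- setNames(c(10, 25, 40, 55)[as.integer(dsn$group)], dsn$sample_id)
  tr <- simulateTrait(dsn, hub_tpm, slope = -0.5, noise_sd = 0, seed = 1)
  bm2 <- matrix(c(10, 25, 40, 55), 1, 4,
                dimnames = list("gH", c("L0", "L4", "L8", "N0")))
  tc3 <- traitCorrelation(bm2, tr, dsn)
  expect_lt(abs(abs(tc3$r) - 1), 1e-12)
  expect_lt(tc3$r, 0)
})
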