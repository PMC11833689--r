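write_test_ibed <- function(rows, path = tempfile(fileext = ".ibed")) {
  header <- paste(c("bait_chr", "bait_start", "bait_end", "bait_name", "oe_chr",
                    "oe_start", "oe_end", "oe_name", "N_reads", "score"),
                  collapse = "\t")
  writeLines(c(paste0("# ", header), rows), path)
  path
}

test_that("interaction loading keeps only scores strictly above the threshold", {
  rows <- c(
    "chr1\t1\t4000\tgA\tchr1\t9001\t12000\t.\t10\t5.0",
    "chr1\t1\t4000\tgA\tchr1\t20001\t24000\t.\t10\t5.01",
    "chr1\t1\t4000\tgA\tchr1\t30001\t34000\t.\t10\t4.2",
    "chr2\t1\t4000\tgB\tchr1\t9001\t12000\t.\t10\t12",
    "chr1\t50001\t54000\tgC\tchr1\t9001\t12000\t.\t10\t80",
    "chr1\t50001\t54000\tgC\tchr1\t70001\t74000\t.\t10\t3",
    "chr1\t50001\t54000\tgC\tchr2\t70001\t74000\t.\t10\t2",
    "chr1\t80001\t84000\tgD\tchr1\t9001\t12000\t.\t10\t1",
    "chr1\t80001\t84000\tgD\tchr1\t20001\t24000\t.\t10\t0.3",
    "chr1\t80001\t84000\tgD\tchr2\t70001\t74000\t.\t10\t4.99"
  )
  rec <- load_interactions(write_test_ibed(rows))
  expect_equal(nrow(rec), 3) # 5.01, 12 and 80 survive; 5.0 is strictly dropped
  expect_true(all(rec$score > 5))
  expect_equal(unname(attr(rec, "parse_report")), c(3, 7))
  # 1-based inclusive input becomes 0-based half-open
  expect_equal(rec$bait_start[1], 0)
  expect_equal(rec$bait_end[1], 4000)
  # cis distance is the midpoint separation; trans rows are flagged
  expect_equal(rec$distance[1], abs(2000 - 22000))
  expect_true(rec$trans[rec$bait_chr == "chr2"][1])
})

test_that("malformed rows fail with a line number and empty results warn", {
  bad <- write_test_ibed("chr1\tx\t4000\tgA\tchr1\t9001\t12000\t.\t10\t7")
  expect_error(load_interactions(bad), "line")
  low <- write_test_ibed("chr1\t1\t4000\tgA\tchr1\t9001\t12000\t.\t10\t2")
  expect_warning(load_interactions(low), "threshold")
})

test_that("network building merges fragments, drops self-edges, and flags promoters", {
  rows <- c(
    "chr1\t1\t4000\tgA\tchr1\t9001\t12000\t.\t10\t7",
    "chr1\t1\t4000\tgA\tchr1\t20001\t24000\tgB\t10\t8",
    "chr1\t1\t4000\tgA\tchr1\t1\t4000\tgA\t10\t9" # self contact
  )
  net <- build_network(load_interactions(write_test_ibed(rows)))
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 2)
  bait <- net$nodes[net$nodes$node_id == "chr1:0-4000", ]
  expect_equal(bait$genes[[1]], "gA")
  expect_true(bait$is_promoter)
  expect_false(net$nodes$is_promoter[net$nodes$node_id == "chr1:9000-12000"])
  # bait node participates in both surviving edges
  expect_equal(sum(net$edges$node_a == "chr1:0-4000" |
                     net$edges$node_b == "chr1:0-4000"), 2)
})

test_that("a triangle of records matches a hand-built adjacency", {
  rows <- c(
    "chr1\t1\t1000\tgA\tchr1\t2001\t3000\tgB\t10\t7",
    "chr1\t2001\t3000\tgB\tchr1\t4001\t5000\tgC\t10\t7",
    "chr1\t4001\t5000\tgC\tchr1\t1\t1000\tgA\t10\t7"
  )
  net <- build_network(load_interactions(write_test_ibed(rows)))
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 3)
  adj <- sort(paste(pmin(net$edges$node_a, net$edges$node_b),
                    pmax(net$edges$node_a, net$edges$node_b)))
  ids <- sort(net$nodes$node_id)
  expect_equal(adj, sort(c(paste(ids[1], ids[2]), paste(ids[2], ids[3]),
                           paste(ids[1], ids[3]))))
})

test_that("coordinate-based promoter assignment overrides file annotations", {
  rows <- c("chr1\t1\t4000\tWRONG\tchr1\t9001\t12000\t.\t10\t7")
  genes <- tibble::tibble(gene_id = "gReal", chrom = "chr1", start = 100,
                          end = 900, strand = "+") |>
    dplyr::mutate(tss = start, tes = end - 1, length = end - start)
  net <- build_network(load_interactions(write_test_ibed(rows)), genes = genes)
  expect_equal(net$nodes$genes[[match("chr1:0-4000", net$nodes$node_id)]], "gReal")
  expect_equal(net$nodes$genes[[match("chr1:9000-12000", net$nodes$node_id)]],
               character(0))
})

test_that("rebuilding from an exported edge list reproduces the network", {
  cfg <- sim_config(n_genes = 80, n_edges = 150, seed = 12)
  g <- sim_genome(cfg)
  net <- sim_network(g$genes, g$ages, cfg)
  f <- tempfile(fileext = ".ibed")
  write_ibed(net, f)
  net2 <- build_network(load_interactions(f))
  # the edge list carries every connected node; isolated nodes have no rows
  connected <- unique(c(net$edges$node_a, net$edges$node_b))
  expect_setequal(net2$nodes$node_id, connected)
  key <- function(n) sort(paste(pmin(n$edges$node_a, n$edges$node_b),
                                pmax(n$edges$node_a, n$edges$node_b)))
  expect_equal(key(net2), key(net))
  # and the gene annotations survive the round trip
  ord <- match(connected, net2$nodes$node_id)
  expect_equal(net2$nodes$genes[ord],
               net$nodes$genes[match(connected, net$nodes$node_id)])
})

test_that("promoter subnetworks induce the promoter-promoter subgraph", {
  # star: promoter center n1, leaves n2..n5 non-promoter
  star <- toy_network(5, cbind(1, 2:5),
                      genes = c(list("g1"), rep(list(character(0)), 4)))
  sub <- promoter_subnetwork(star)
  expect_equal(nrow(sub$nodes), 1)
  expect_equal(nrow(sub$edges), 0)
  # inclusive mode keeps promoter-other-end contacts
  incl <- promoter_subnetwork(star, mode = "inclusive")
  expect_equal(nrow(incl$edges), 4)
  # all-promoter network is unchanged
  all_prom <- toy_network(4, cbind(c(1, 2), c(3, 4)))
  expect_equal(promoter_subnetwork(all_prom)$edges, all_prom$edges)
  # mixed 6-node toy vs brute-force induced subgraph
  mixed <- toy_network(6, cbind(c(1, 1, 2, 3, 5), c(2, 4, 3, 5, 6)),
                       genes = list("g1", "g2", character(0), "g4",
                                    "g5", character(0)))
  sub2 <- promoter_subnetwork(mixed)
  prom_ids <- mixed$nodes$node_id[mixed$nodes$is_promoter]
  brute <- mixed$edges[mixed$edges$node_a %in% prom_ids &
                         mixed$edges$node_b %in% prom_ids, ]
  expect_equal(sub2$edges, brute)
  expect_lte(nrow(sub2$edges), nrow(mixed$edges))
})

test_that("feature mapping applies OR for binary and mean for continuous", {
  net <- toy_network(3, cbind(1, 2),
                     genes = list(c("g1", "g2"), "g3", character(0)))
  fb <- map_feature(net, c(g1 = 1, g2 = 0, g3 = 0), kind = "binary")
  expect_equal(fb$value, c(1, 0, NA_real_))
  fc <- map_feature(net, c(g1 = 0.2, g2 = 0.6, g3 = 1), kind = "continuous")
  expect_equal(fc$value, c(0.4, 1, NA_real_))
  expect_warning(map_feature(net, tibble::tibble(gene_id = character(),
                                                 value = numeric())),
                 "Empty")
})

test_that("raising the score threshold never adds interactions", {
  cfg <- sim_config(n_genes = 60, n_edges = 120, seed = 13)
  g <- sim_genome(cfg)
  net <- sim_network(g$genes, g$ages, cfg)
  f <- tempfile(fileext = ".ibed")
  write_ibed(net, f)
  n5 <- nrow(load_interactions(f, score_threshold = 5))
  n10 <- nrow(load_interactions(f, score_threshold = 10))
  n20 <- nrow(load_interactions(f, score_threshold = 20))
  expect_true(n20 <= n10 && n10 <= n5)
})
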