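test_that("ingest aggregates duplicates, drops zeros and builds the meta-network", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("realization\tconsumer\tresource\tcount",
               "Apr\tA\tx\t2", "Apr\tA\ty\t1", "May\tA\tx\t1",
               "Apr\tA\tx\t3", "May\tB\ty\t0"), path)
  series <- read_interaction_table(path)
  expect_s3_class(series, "network_series")
  expect_identical(series$ids, c("Apr", "May"))
  apr <- series$networks[["Apr"]]
  expect_equal(apr$edges$weight[apr$edges$consumer == "A" &
                                  apr$edges$resource == "x"], 5)
  meta <- series$meta
  expect_equal(sort(paste(meta$edges$consumer, meta$edges$resource)),
               c("A x", "A y"))
  expect_equal(meta$edges$weight[meta$edges$resource == "x"], 6)
  # zero-count row was dropped entirely: B never occurs
  expect_false("B" %in% species(meta))
})

test_that("ingest errors name the offending column or row", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("realization\tconsumer\tprey\tcount", "Apr\tA\tx\t2"), path)
  expect_error(read_interaction_table(path), "resource")
  writeLines(c("realization\tconsumer\tresource\tcount",
               "Apr\tA\tx\ttwo"), path)
  expect_error(read_interaction_table(path), "row 1")
  writeLines(c("realization\tconsumer\tresource\tcount",
               "Apr\tA\tx\t-1"), path)
  expect_error(read_interaction_table(path), "negative")
  writeLines(c("realization\tconsumer\tresource\tcount",
               "Apr\tA\tx\t0"), path)
  expect_error(read_interaction_table(path), "no interactions")
})

test_that("round-trip write/read reproduces the series", {
  set.seed(7)
  series <- random_series(3L, sprintf("A%d", 1:4), sprintf("x%d", 1:5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_interaction_table(series, path,
                          provenance = list(note = "round-trip fixture"))
  back <- read_interaction_table(path)
  expect_identical(back$ids, series$ids)
  for (id in series$ids) {
    expect_equal(back$networks[[id]]$edges, series$networks[[id]]$edges)
  }
  expect_equal(back$meta$edges, series$meta$edges)
})

test_that("meta-network weights conserve the per-realization sums", {
  set.seed(11)
  for (rep in 1:20) {
    series <- random_series(4L, sprintf("A%d", 1:5), sprintf("x%d", 1:5))
    meta <- series$meta
    pooled <- do.call(rbind, lapply(series$networks, `[[`, "edges"))
    for (i in seq_len(nrow(meta$edges))) {
      expected <- sum(pooled$weight[pooled$consumer == meta$edges$consumer[i] &
                                      pooled$resource == meta$edges$resource[i]])
      expect_identical(meta$edges$weight[i], expected)
    }
    expect_identical(total_weight(meta),
                     sum(vapply(series$networks, total_weight, numeric(1))))
  }
})

test_that("single-realization meta equals the realization", {
  net <- net_from("A-x" = 1, "B-y" = 2)
  expect_equal(build_meta_network(list(net))$edges, net$edges)
  expect_error(build_meta_network(list()), "empty")
})

test_that("guild namespaces must stay disjoint", {
  expect_error(bipartite_network(data.frame(consumer = c("A", "x"),
                                            resource = c("x", "y"),
                                            weight = c(1, 1))),
               "both guilds")
  # and across realizations of a series
  n1 <- net_from("A-x" = 1)
  n2 <- bipartite_network(data.frame(consumer = "x", resource = "z", weight = 1))
  expect_error(network_series(list(n1, n2)), "guilds")
})

test_that("proportion conversion normalizes and is idempotent", {
  net <- net_from("A-x" = 3, "A-y" = 1)
  prop <- to_proportions(net)
  expect_equal(prop$edges$weight, c(0.75, 0.25))
  expect_equal(to_proportions(prop)$edges$weight, prop$edges$weight)
  expect_equal(to_proportions(net_from("A-x" = 2, "B-x" = 2, "B-y" = 1))$edges$weight,
               c(0.4, 0.4, 0.2))
  expect_error(to_proportions(empty_net()), "empty")
})

test_that("species removal drops incident edges and isolated vertices", {
  net <- net_from("A-x" = 1, "B-x" = 1, "B-y" = 1)
  reduced <- remove_species(net, "B")
  expect_equal(reduced$edges$consumer, "A")
  expect_false("y" %in% species(reduced))          # y lost its only edge
  expect_equal(remove_species(net, "Z")$edges, net$edges)  # absent: no-op
  # original untouched
  expect_equal(n_edges(net), 3L)
})

test_that("removal on a series empties but retains realizations", {
  s <- network_series(list(net_from(c("A-x", "B-y")), net_from("A-y")),
                      ids = c("r1", "r2"))
  reduced <- remove_species(s, "A")
  expect_identical(reduced$ids, s$ids)
  expect_true(is_empty(reduced$networks[["r2"]]))
  expect_equal(reduced$networks[["r1"]]$edges$consumer, "B")
  expect_equal(species(reduced$meta), c("B", "y"))
  expect_error(remove_species(s, c("A", "B")), "empties every realization")
})

test_that("remove-then-meta commutes with meta-then-remove", {
  set.seed(23)
  for (rep in 1:10) {
    series <- random_series(3L, sprintf("A%d", 1:4), sprintf("x%d", 1:4))
    sp <- sample(species(series$meta), 1L)
    via_series <- remove_species(series, sp)$meta
    via_meta <- remove_species(series$meta, sp)
    expect_equal(via_series$edges, via_meta$edges)
  }
})

test_that("edge alignment classifies rewiring vs turnover edges", {
  # all four species shared: one-sided edges are all rewiring
  al <- align_edges(net_from(c("A-x", "A-y", "B-x")), net_from(c("A-x", "B-y")))
  expect_equal(al$counts[c("a", "b", "c", "b_rw", "c_rw", "b_st", "c_st")],
               list(a = 1L, b = 2L, c = 1L, b_rw = 2L, c_rw = 1L,
                    b_st = 0L, c_st = 0L))
  # unshared endpoints push one-sided edges into turnover
  al <- align_edges(net_from(c("A-x", "B-y")), net_from(c("A-x", "C-x")))
  expect_equal(al$counts$a, 1L)
  expect_equal(al$counts$b_st, 1L)
  expect_equal(al$counts$c_st, 1L)
  expect_equal(al$counts$b_rw + al$counts$c_rw, 0L)
  # identical networks: everything shared
  m <- net_from("A-x" = 2, "B-y" = 3)
  al <- align_edges(m, m)
  expect_equal(al$counts$a, 2L)
  expect_equal(al$counts$b + al$counts$c, 0L)
  expect_true(all(al$table$class == "shared"))
})

test_that("alignment classes partition the edge union for random pairs", {
  set.seed(31)
  for (rep in 1:50) {
    m <- random_net()
    n <- random_net()
    al <- align_edges(m, n)
    ct <- al$counts
    expect_identical(ct$b, ct$b_rw + ct$b_st)
    expect_identical(ct$c, ct$c_rw + ct$c_st)
    expect_identical(ct$a + ct$b + ct$c, nrow(al$table))
    # and agrees with the explicit per-edge oracle
    oracle <- oracle_classify(m, n)
    key <- function(d) paste(d$consumer, d$resource)
    expect_setequal(paste(key(al$table), al$table$class),
                    paste(key(oracle), oracle$class))
  }
})

test_that("incidence-matrix export lays out consumers x resources", {
  net <- net_from("A-x" = 2, "B-y" = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  mat <- write_incidence_matrix(net, path)
  expect_equal(dim(mat), c(2L, 2L))
  expect_equal(mat["A", "x"], 2)
  expect_equal(mat["B", "x"], 0)
  on_disk <- utils::read.table(path, header = TRUE, sep = "\t",
                               check.names = FALSE)
  expect_equal(on_disk$consumer, c("A", "B"))
})
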