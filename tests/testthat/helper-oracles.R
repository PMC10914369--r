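# Independent oracles and fixture builders. These deliberately avoid the
# package's align_edges()/partition_pair() code paths: edges are
# enumerated one by one and classified by explicit endpoint-occurrence
# tests, and sums are accumulated term by term.

net_from <- function(...) {
  # net_from("A-x" = 2, "B-y" = 1): edge spec as consumer-resource = weight
  spec <- list(...)
  if (length(spec) == 1L && is.null(names(spec)) && is.character(spec[[1L]])) {
    spec <- stats::setNames(as.list(rep(1, length(spec[[1L]]))), spec[[1L]])
  }
  parts <- strsplit(names(spec), "-", fixed = TRUE)
  bipartite_network(data.frame(
    consumer = vapply(parts, `[`, "", 1L),
    resource = vapply(parts, `[`, "", 2L),
    weight = as.numeric(unlist(spec))))
}

empty_net <- function() {
  bipartite_network(data.frame(consumer = character(),
                               resource = character(), weight = numeric()))
}

# every edge of the union, one row per edge, classified from scratch
oracle_classify <- function(m, n) {
  em <- paste(m$edges$consumer, m$edges$resource, sep = "|")
  en <- paste(n$edges$consumer, n$edges$resource, sep = "|")
  keys <- unique(c(em, en))
  do.call(rbind, lapply(keys, function(k) {
    cr <- strsplit(k, "|", fixed = TRUE)[[1L]]
    in_m <- k %in% em
    in_n <- k %in% en
    c_in_both <- (cr[1L] %in% m$edges$consumer) && (cr[1L] %in% n$edges$consumer)
    r_in_both <- (cr[2L] %in% m$edges$resource) && (cr[2L] %in% n$edges$resource)
    cls <- if (in_m && in_n) "shared"
           else if (c_in_both && r_in_both) "unique_rw" else "unique_st"
    data.frame(consumer = cr[1L], resource = cr[2L],
               u = if (in_m) m$edges$weight[em == k] else 0,
               v = if (in_n) n$edges$weight[en == k] else 0,
               class = cls, stringsAsFactors = FALSE)
  }))
}

# term-by-term partition oracle (binary and quantitative, both frameworks)
oracle_partition <- function(m, n, framework = "framework2",
                             metric = "bray_curtis", proportions = TRUE) {
  if (metric == "bray_curtis" && proportions) {
    m$edges$weight <- m$edges$weight / sum(m$edges$weight)
    n$edges$weight <- n$edges$weight / sum(n$edges$weight)
  }
  tab <- oracle_classify(m, n)
  if (metric == "sorensen") {
    a <- b <- cc <- b_rw <- c_rw <- b_st <- c_st <- 0
    for (i in seq_len(nrow(tab))) {
      if (tab$u[i] > 0 && tab$v[i] > 0) a <- a + 1
      if (tab$u[i] > 0 && tab$v[i] == 0) {
        b <- b + 1
        if (tab$class[i] == "unique_rw") b_rw <- b_rw + 1 else b_st <- b_st + 1
      }
      if (tab$v[i] > 0 && tab$u[i] == 0) {
        cc <- cc + 1
        if (tab$class[i] == "unique_rw") c_rw <- c_rw + 1 else c_st <- c_st + 1
      }
    }
    den <- 2 * a + b + cc
    beta_int <- (b + cc) / den
    if (framework == "framework2") {
      beta_rw <- (b_rw + c_rw) / den
      beta_st <- (b_st + c_st) / den
    } else {
      den_rw <- 2 * a + b_rw + c_rw
      beta_rw <- if (den_rw == 0) 0 else (b_rw + c_rw) / den_rw
      beta_st <- beta_int - beta_rw
    }
  } else {
    num_all <- num_rw <- num_st <- den <- den_rw <- 0
    for (i in seq_len(nrow(tab))) {
      d <- abs(tab$u[i] - tab$v[i])
      s <- tab$u[i] + tab$v[i]
      num_all <- num_all + d
      den <- den + s
      if (tab$class[i] %in% c("shared", "unique_rw")) {
        num_rw <- num_rw + d
        den_rw <- den_rw + s
      } else {
        num_st <- num_st + d
      }
    }
    beta_int <- num_all / den
    if (framework == "framework2") {
      beta_rw <- num_rw / den
      beta_st <- num_st / den
    } else {
      beta_rw <- if (den_rw == 0) 0 else num_rw / den_rw
      beta_st <- beta_int - beta_rw
    }
  }
  list(beta_int = beta_int, beta_rw = beta_rw, beta_st = beta_st)
}

# random small network over bounded species pools, always nonempty
random_net <- function(max_consumers = 5L, max_resources = 5L,
                       consumers = sprintf("A%d", seq_len(max_consumers)),
                       resources = sprintf("x%d", seq_len(max_resources)),
                       integer_weights = TRUE) {
  pairs <- expand.grid(consumer = consumers, resource = resources,
                       stringsAsFactors = FALSE)
  k <- sample.int(nrow(pairs), sample.int(nrow(pairs), 1L))
  w <- if (integer_weights) sample.int(9L, length(k), replace = TRUE)
       else stats::runif(length(k), 0.1, 5)
  bipartite_network(data.frame(consumer = pairs$consumer[k],
                               resource = pairs$resource[k], weight = w))
}

random_series <- function(n_realizations, consumers, resources,
                          occupancy = 0.7) {
  nets <- replicate(n_realizations, {
    cs <- consumers[stats::runif(length(consumers)) < occupancy]
    rs <- resources[stats::runif(length(resources)) < occupancy]
    if (length(cs) == 0L) cs <- consumers[1L]
    if (length(rs) == 0L) rs <- resources[1L]
    random_net(consumers = cs, resources = rs)
  }, simplify = FALSE)
  network_series(nets)
}

# power-iteration eigenvector oracle, scaled to max 1. A bipartite
# adjacency has a symmetric spectrum (+/- lambda_max), so plain power
# iteration oscillates; iterating on A + I shifts the spectrum and leaves
# the eigenvectors unchanged.
oracle_eigenvector <- function(net, iters = 100000L, tol = 1e-14) {
  sp <- species(net)
  adj <- matrix(0, length(sp), length(sp), dimnames = list(sp, sp))
  adj[cbind(net$edges$consumer, net$edges$resource)] <- 1
  adj <- adj + t(adj)
  x <- rep(1, length(sp))
  for (i in seq_len(iters)) {
    x_new <- adj %*% x + x
    x_new <- x_new / sqrt(sum(x_new^2))
    if (max(abs(x_new - x)) < tol) break
    x <- x_new
  }
  stats::setNames(as.numeric(x / max(x)), sp)
}
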