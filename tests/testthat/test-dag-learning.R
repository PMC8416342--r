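test_that("BIC family score has its multinomial closed form", {
  ds <- discrete_dataset(data.frame(x = c(0L, 0L, 1L, 1L)),
                         levels = c(x = 2L))
  empty <- dag_structure("x")
  expect_equal(bic_score(ds, empty), 4 * log(0.5) - log(4) / 2,
               tolerance = 1e-12)

  # decomposability: a 3-node score is the sum of its family scores
  ds3 <- chain_data(200, seed = 3)
  dag <- dag_structure(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  total <- bic_score(ds3, dag)
  part <- bic_score(ds3, dag_structure(c("A", "B", "C"), rbind(c("A", "B")))) -
    bic_score(ds3, dag_structure(c("A", "B", "C"))) +
    bic_score(ds3, dag_structure(c("A", "B", "C"), rbind(c("B", "C"))))
  expect_equal(total, part, tolerance = 1e-10)

  # adding an edge between independent variables lowers the score
  set.seed(4)
  ind <- discrete_dataset(
    data.frame(A = sample(0:1, 5000, TRUE), B = sample(0:1, 5000, TRUE)),
    levels = c(A = 2L, B = 2L))
  s0 <- bic_score(ind, dag_structure(c("A", "B")))
  s1 <- bic_score(ind, dag_structure(c("A", "B"), rbind(c("A", "B"))))
  expect_lt(s1, s0)

  # parameter-cap guard
  wide <- discrete_dataset(
    data.frame(A = sample(0:1, 50, TRUE), B = sample(0:1, 50, TRUE)),
    levels = c(A = 2L, B = 2L))
  expect_error(
    bic_score(wide, dag_structure(c("A", "B"), rbind(c("A", "B"))),
              max_params = 1),
    "parameter cap")
})

test_that("DAG structures reject cycles, self-loops and duplicates", {
  expect_error(dag_structure(c("A", "B"), rbind(c("A", "A"))), "self-loops")
  expect_error(dag_structure(c("A", "B"),
                             rbind(c("A", "B"), c("A", "B"))), "duplicate")
  expect_error(dag_structure(c("A", "B", "C"),
                             rbind(c("A", "B"), c("B", "C"), c("C", "A"))),
               "cycle")
  ok <- dag_structure(c("A", "B", "C"), rbind(c("A", "B"), c("A", "C")))
  expect_true(is_acyclic(ok))
})

test_that("hill climbing returns the empty graph for independent data", {
  set.seed(5)
  ind <- discrete_dataset(
    data.frame(A = sample(0:1, 5000, TRUE), B = sample(0:1, 5000, TRUE)),
    levels = c(A = 2L, B = 2L))
  dag <- hill_climb(ind)
  expect_equal(nrow(dag_edges(dag)), 0L)
})

test_that("hill climbing recovers a chain skeleton and is deterministic", {
  ds <- chain_data(5000, flip = 0.2, seed = 6)
  dag <- hill_climb(ds)
  e <- dag_edges(dag)
  skel <- apply(e, 1, function(r) paste(sort(r), collapse = "-"))
  expect_setequal(skel, c("A-B", "B-C"))
  expect_identical(dag_edges(hill_climb(ds)), e)
  # score trajectory strictly increases
  expect_true(all(diff(c(attr(dag, "trajectory"))) > 0))
  # respondent order does not matter
  perm <- structure(list(codes = ds$codes[sample(nrow(ds$codes)), ],
                         nlevels = ds$nlevels, items = ds$items),
                    class = "discrete_dataset")
  expect_identical(dag_edges(hill_climb(perm)), e)
})

test_that("hill climbing is bracketed by the empty graph and the global optimum", {
  hits <- 0
  reps <- 25
  for (r in seq_len(reps)) {
    ds <- chain_data(300, flip = runif(1, 0.1, 0.45), seed = 600 + r)
    best <- max(vapply(enumerate_dags3(), function(d) bic_score(ds, d),
                       numeric(1)))
    hc <- attr(hill_climb(ds), "score")
    empty <- bic_score(ds, dag_structure(c("A", "B", "C")))
    expect_gte(hc, empty)
    expect_lte(hc, best + 1e-9)
    if (abs(hc - best) < 1e-9) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("bootstrap averaging keeps books consistent and respects B = 1", {
  ds <- chain_data(500, seed = 8)
  one <- bootstrap_average(ds, B = 1, seed = 3)
  expect_true(all(one$pairs$presence_strength %in% c(0, 1)))
  # the single-resample graph is the final graph
  set.seed(3)
  idx <- sample.int(500, 500, replace = TRUE)
  boot <- structure(list(codes = ds$codes[idx, ], nlevels = ds$nlevels,
                         items = ds$items), class = "discrete_dataset")
  expect_setequal(paste(one$edges$from, one$edges$to),
                  paste(dag_edges(hill_climb(boot))[, 1],
                        dag_edges(hill_climb(boot))[, 2]))

  avg <- bootstrap_average(ds, B = 40, seed = 9)
  # conservation: absent + forward + backward = B for every pair
  expect_true(all(avg$pairs$n_forward + avg$pairs$n_backward <= 40))
  expect_true(all(avg$pairs$presence_strength >= 0 &
                    avg$pairs$presence_strength <= 1))
  present <- avg$pairs$presence_strength > 0
  expect_true(all(abs(avg$pairs$direction_strength[present] +
                        (avg$pairs$n_backward[present] /
                           (avg$pairs$n_forward[present] +
                              avg$pairs$n_backward[present])) - 1) < 1e-12))
  # the averaged graph is acyclic by construction
  expect_true(is_acyclic(dag_structure(avg$nodes,
                                       as.matrix(avg$edges[, 1:2]))))
})

test_that("bootstrap averaging keeps true chain edges and drops the shortcut", {
  ds <- chain_data(2000, flip = 0.15, seed = 10)
  avg <- bootstrap_average(ds, B = 200, seed = 11, threshold = 0.5)
  skel <- apply(as.matrix(avg$edges[, 1:2]), 1,
                function(r) paste(sort(r), collapse = "-"))
  expect_setequal(skel, c("A-B", "B-C"))
  expect_false("A-C" %in% skel)
  expect_true(all(avg$edges$presence_strength >= 0.5))
})

test_that("averaged DAGs export to edge-list CSV and DOT", {
  ds <- chain_data(400, seed = 12)
  avg <- bootstrap_average(ds, B = 20, seed = 13)
  csv <- withr::local_tempfile(fileext = ".csv")
  dot <- withr::local_tempfile(fileext = ".dot")
  write_dag_csv(avg, csv)
  back <- read.csv(csv)
  expect_identical(names(back),
                   c("from", "to", "presence_strength", "direction_strength"))
  write_dag_dot(avg, dot)
  lines <- readLines(dot)
  expect_match(lines[1], "digraph")
  expect_true(any(grepl("->", lines)))
})
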