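test_that("assignment costs weight false negatives 3.8 times", {
  inst <- random_instance(5)
  ns <- nrow(inst$prep$node_slots); ne <- nrow(inst$prep$edges)
  gold <- bioevent:::new_assignment(rep(FALSE, ns), rep("NEG", ne))
  expect_equal(assignment_cost(gold, gold), 0)
  # one missed trigger label
  g1 <- gold; g1$node_pos[1] <- TRUE
  expect_equal(assignment_cost(g1, gold), 3.8)
  # one spurious edge plus one missed edge
  g2 <- gold; g2$edge_lab[1] <- "THEME"
  p2 <- gold; p2$edge_lab[2] <- "THEME"
  expect_equal(assignment_cost(g2, p2), 1 + 3.8)
  # role substitution counts one FP plus one FN
  p3 <- gold; p3$edge_lab[1] <- "CAUSE"
  expect_equal(assignment_cost(g2, p3), 1 + 3.8)
  expect_error(assignment_cost(g2, bioevent:::new_assignment(
    rep(FALSE, ns + 1L), rep("NEG", ne))), "different masks")
})

test_that("the PA update achieves exactly the required margin", {
  # single-feature closed form: phi = {f}, gold positive, pred negative,
  # zero weights, cost c  =>  delta = 2 phi, tau = c / 4, new margin = c
  labels <- c("Gene_expression", paste0("EDGE:", c("THEME", "CAUSE", "NEG")))
  prep <- list(
    node_slots = data.frame(tok = 0L, label = "Gene_expression", col = 1L),
    node_phi = list(`0` = list(idx = 1L, val = 1)),
    edge_phi = list(list(idx = 2L, val = 1)),
    edges = data.frame(src = 0L, tgt = 1L),
    edge_cols = 2:4, cand_tok = 0L, protein_tok = 1L, n_tokens = 2L)
  W <- matrix(0, 2, 4, dimnames = list(NULL, labels))
  gold <- bioevent:::new_assignment(TRUE, "THEME")
  pred <- bioevent:::new_assignment(FALSE, "NEG")
  up <- pa_update(W, prep, gold, pred, cost = 4.8)
  # |Delta|^2 = (2*1)^2 on the node feature + 1 + 1 on the edge columns
  expect_equal(up$norm2, 6)
  expect_equal(up$tau, 4.8 / 6)
  s_gold <- assignment_score(gold, prep, up$W)
  s_pred <- assignment_score(pred, prep, up$W)
  expect_equal(s_gold - s_pred, 4.8)

  # identical assignments leave the weights untouched
  same <- pa_update(W, prep, gold, gold, cost = 1)
  expect_equal(same$W, W)
  expect_equal(same$tau, 0)
})

test_that("margin holds after every update on random instances", {
  checked <- 0L
  for (trial in 1:60) {
    inst <- random_instance(3000 + trial)
    W2 <- random_instance(6000 + trial)$W
    gold <- decode(inst$prep, W2)$pass1
    pred <- decode(inst$prep, inst$W)$pass1
    if (bioevent:::assignments_equal(gold, pred)) next
    cost <- assignment_cost(gold, pred)
    up <- pa_update(inst$W, inst$prep, gold, pred, cost)
    if (up$tau == 0) {
      # margin was already satisfied before the update
      dots <- bioevent:::.sentence_dots(inst$prep, inst$W)
      expect_gte(assignment_score(gold, inst$prep, inst$W, dots) -
                   assignment_score(pred, inst$prep, inst$W, dots), cost)
      next
    }
    s_gold <- assignment_score(gold, inst$prep, up$W)
    s_pred <- assignment_score(pred, inst$prep, up$W)
    expect_gte(s_gold - s_pred, cost - 1e-8)
    checked <- checked + 1L
  }
  expect_gte(checked, 20L)
})

test_that("an all-negative gold corpus trains a zero model", {
  corpus <- small_corpus(seed = 41, n_documents = 2, spd = 4)
  corpus <- lapply(corpus, function(d) { d$events <- list(); d })
  lex <- prune(build_trigger_lexicons(small_corpus(seed = 41,
                                                   n_documents = 2, spd = 4)))
  fit <- train_baseline(corpus, lex,
                        config = training_config(passes = 4, init_rounds = 0))
  for (m in fit$models) expect_true(all(m$W == 0))
})

test_that("a separable one-sentence corpus is learned and averaging matches
          an explicit accumulator", {
  corpus <- small_corpus(seed = 55, n_documents = 1, spd = 3)
  lex <- prune(build_trigger_lexicons(corpus))
  slex <- prune(build_trigger_lexicons(corpus, stemmed = TRUE))
  prepc <- prepare_corpus(corpus, lex, slex)
  cfg <- training_config(passes = 6)
  fit <- train_baseline(prepc, config = cfg)

  # the final raw model decodes every gold graph
  for (rec in prepc$sentences) {
    if (is.null(rec$gold_assign)) next
    pred <- decode(rec, fit$final_W)$pass1
    expect_true(bioevent:::assignments_equal(pred, rec$gold_assign))
  }

  # accumulator oracle: naive re-run summing interim matrices explicitly
  n <- max(prepc$fidx$n, 1L)
  W <- matrix(0, n, length(prepc$all_labels),
              dimnames = list(NULL, prepc$all_labels))
  acc <- W * 0; t <- 0L
  snapshots <- list()
  for (pass in seq_len(cfg$passes)) {
    for (rec in prepc$sentences) {
      t <- t + 1L
      if (!is.null(rec$gold_assign)) {
        pred <- decode(rec, W)$pass1
        if (!bioevent:::assignments_equal(pred, rec$gold_assign)) {
          cost <- assignment_cost(rec$gold_assign, pred, cfg$fn_cost_ratio)
          W <- pa_update(W, rec, rec$gold_assign, pred, cost)$W
        }
      }
      acc <- acc + W
    }
    snapshots[[pass]] <- acc / t
  }
  for (pass in seq_len(cfg$passes))
    expect_equal(fit$models[[pass]]$W, snapshots[[pass]],
                 tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("the basic constraint compares typed structure, not triggers", {
  doc <- fixture_doc()
  g_gold <- events_to_graph(doc, 1)
  tokens <- doc$sentences[[1]]$tokens
  st_gold <- bioevent:::typed_structure(g_gold, tokens)
  expect_true(basic_constraint(st_gold, st_gold))
  # same typed structure anchored at a different word
  g_moved <- bioevent:::new_event_graph(
    7L,
    node_labels = list(`3` = "Gene_expression", `4` = "Positive_regulation"),
    edges = data.frame(src = c(4L, 4L, 3L), tgt = c(3L, 0L, 5L),
                       role = c("THEME", "CAUSE", "THEME")))
  expect_true(basic_constraint(bioevent:::typed_structure(g_moved, tokens),
                               st_gold))
  # dropping the nested event breaks the constraint
  g_dropped <- bioevent:::new_event_graph(
    7L, node_labels = list(`3` = "Gene_expression"),
    edges = data.frame(src = 3L, tgt = 5L, role = "THEME"))
  expect_false(basic_constraint(bioevent:::typed_structure(g_dropped, tokens),
                                st_gold))
})

test_that("the confidence constraint is an exact relative-improvement gate", {
  expect_true(confidence_constraint(10, 10, 0))
  expect_true(confidence_constraint(13, 10, 0.3))
  expect_false(confidence_constraint(12.9, 10, 0.3))
  expect_false(confidence_constraint(-Inf, 10, 0))
  # near-zero current scores use the epsilon floor
  expect_true(confidence_constraint(1e-6, 0, 0.3))
})

test_that("the non-overlapping and distance constraints follow the
          two-trigger example", {
  tokens <- sentence5_tokens()
  # gold: two distinct PosReg triggers, "high levels" and 'augmented'
  gold <- bioevent:::new_event_graph(
    9L,
    node_labels = list(`3` = "Positive_regulation",
                       `8` = "Positive_regulation"),
    edges = data.frame(src = c(3L, 8L), tgt = c(0L, 0L), role = "THEME"),
    trigger_spans = data.frame(
      index = c(3L, 8L), label = "Positive_regulation",
      char_start = c(tokens$char_start[3], tokens$char_start[9]),
      char_end = c(tokens$char_end[4], tokens$char_end[9]),
      text = c("high levels", "augmented"), stringsAsFactors = FALSE))
  # candidate collapsing both onto one word violates NOC
  one <- bioevent:::new_event_graph(
    9L, node_labels = list(`3` = "Positive_regulation"),
    edges = data.frame(src = 3L, tgt = 0L, role = "THEME"))
  expect_false(non_overlapping_constraint(one, gold))
  expect_true(non_overlapping_constraint(gold, gold))
  # absent event types are vacuously satisfied
  expect_true(non_overlapping_constraint(one, bioevent:::new_event_graph(9L)))

  # distance: 'levels' and 'augmented' are four word tokens apart, so a
  # candidate lacking the second anchor fails for beta <= 3
  expect_true(distance_constraint(gold, gold, 0, tokens))
  for (beta in 0:3)
    expect_false(distance_constraint(one, gold, beta, tokens))
  expect_true(distance_constraint(one, gold, 4, tokens))
  expect_true(distance_constraint(one, gold, 100, tokens))
})

test_that("unconstrained EM accepts a superset of constrained round-6 updates", {
  corpus <- small_corpus(seed = 67, n_documents = 6, spd = 8, rate = 0.4)
  lex <- prune(build_trigger_lexicons(corpus))
  slex <- prune(build_trigger_lexicons(corpus, stemmed = TRUE))
  prepc <- prepare_corpus(corpus, lex, slex)
  cfg_con <- training_config(passes = 8, alpha = 0.1, beta = 2,
                             use_noc = TRUE)
  cfg_pure <- training_config(passes = 8, alpha = -Inf, beta = Inf,
                              use_noc = FALSE, use_basic = FALSE)
  fit_con <- informed_em(prepc, config = cfg_con)
  fit_pure <- informed_em(prepc, config = cfg_pure)
  # before any update both runs share the same weights, so the first
  # E step decodes identically: constrained acceptances are a subset
  r6_con <- fit_con$history$sentence[fit_con$history$round == 6L]
  r6_pure <- fit_pure$history$sentence[fit_pure$history$round == 6L]
  expect_true(all(r6_con %in% r6_pure))
  expect_gte(nrow(fit_pure$history), nrow(fit_con$history))
})

test_that("adjusted graphs keep decoding to the gold typed structure", {
  corpus <- small_corpus(seed = 71, n_documents = 6, spd = 8, rate = 0.4)
  lex <- prune(build_trigger_lexicons(corpus))
  slex <- prune(build_trigger_lexicons(corpus, stemmed = TRUE))
  prepc <- prepare_corpus(corpus, lex, slex)
  fit <- informed_em(prepc, config = training_config(passes = 8, alpha = 0.05,
                                                     beta = 2))
  expect_gte(nrow(fit$history), 1L)  # the inconsistent corpus yields updates
  for (si in seq_along(prepc$sentences)) {
    rec <- prepc$sentences[[si]]
    if (is.null(rec$gold_assign)) next
    if (!fit$updated[si]) next
    st <- bioevent:::typed_structure(fit$adjusted[[si]], rec$tokens)
    st_gold <- bioevent:::typed_structure(rec$gold_graph, rec$tokens)
    expect_true(basic_constraint(st, st_gold))
  }
})
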