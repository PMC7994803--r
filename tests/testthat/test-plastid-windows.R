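mcmctree_ac_windows <- function() {
  list(Rho = time_interval(1675, 1281), Cry = time_interval(1658, 440),
       Och = time_interval(1298, 622), Hap = time_interval(1943, 579),
       Myz = time_interval(1520, 696))
}

test_that("transfer_window reproduces the published pairwise intersections", {
  tw <- transfer_window(time_interval(1675, 1281), time_interval(1658, 440))
  expect_true(tw$feasible)
  expect_equal(tw$window$older, 1658)
  expect_equal(tw$window$younger, 1281)
  expect_equal(tw$width, 377)
  tw2 <- transfer_window(time_interval(1658, 440), time_interval(1943, 579))
  expect_equal(c(tw2$window$older, tw2$window$younger, tw2$width),
               c(1658, 579, 1079))
  tw3 <- transfer_window(time_interval(800, 700), time_interval(600, 500))
  expect_false(tw3$feasible)
  expect_null(tw3$window)
  expect_equal(tw3$width, -100)  # overlap deficit
})

test_that("transfer_window is commutative, idempotent and width-bounded", {
  set.seed(31)
  for (i in 1:200) {
    a <- sort(runif(2, 0, 2000))
    b <- sort(runif(2, 0, 2000))
    ia <- time_interval(a[2], a[1])
    ib <- time_interval(b[2], b[1])
    ab <- transfer_window(ia, ib)
    ba <- transfer_window(ib, ia)
    expect_equal(ab$width, ba$width)
    aa <- transfer_window(ia, ia)
    expect_equal(c(aa$window$older, aa$window$younger), c(ia$older, ia$younger))
    expect_lte(ab$width, min(interval_width(ia), interval_width(ib)))
  }
})

test_that("scenario engines reproduce the published event windows", {
  w <- mcmctree_ac_windows()
  st <- scenario_windows(scenario_preset("stiller"), w)
  expect_equal(nrow(st), 4L)
  expect_equal(st$width[st$donor == "Rho"], 377)
  expect_equal(st$width[st$donor == "Och" & st$recipient == "Myz"], 602)
  bo <- scenario_windows(scenario_preset("bodyl"), w)
  hm <- bo[bo$donor == "Hap", ]
  expect_equal(c(hm$older, hm$younger, hm$width), c(1520, 696, 824))
  ch <- bo[bo$recipient == "Hap", ]
  expect_equal(ch$width, 1079)
  # idempotence: identical availability for all lineages
  same <- lapply(w, function(x) time_interval(1200, 800))
  st2 <- scenario_windows(scenario_preset("stiller"), same)
  expect_true(all(st2$older == 1200 & st2$younger == 800))
  expect_error(scenario_windows(scenario_preset("stiller"), w[-1]),
               "Rho")
})

test_that("recomputed widths equal older - younger exactly on integer bounds", {
  w <- mcmctree_ac_windows()
  for (sc in c("stiller", "bodyl")) {
    ev <- scenario_windows(scenario_preset(sc), w)
    expect_equal(ev$width, ev$older - ev$younger)
    expect_equal(round_half_away(ev$width), ev$width)  # integer inputs
  }
})

test_that("scenario envelope matches direct max/min arithmetic", {
  w <- mcmctree_ac_windows()
  bo <- scenario_windows(scenario_preset("bodyl"), w)
  env <- scenario_envelope(bo)
  expect_equal(env$window$older, 1658)
  expect_equal(env$window$younger, 579)
  expect_equal(env$width, 1079)
  st <- scenario_windows(scenario_preset("stiller"), w)
  env2 <- scenario_envelope(st)
  # independent arithmetic over the four recomputed windows
  expect_equal(env2$window$older, max(st$older))
  expect_equal(env2$window$younger, min(st$younger))
  expect_equal(env2$width, max(st$older) - min(st$younger))
  one <- st[1, ]
  env3 <- scenario_envelope(one)
  expect_equal(c(env3$window$older, env3$window$younger),
               c(one$older, one$younger))
  bad <- st
  bad$feasible[2] <- FALSE
  expect_error(scenario_envelope(bad), "infeasible")
})

test_that("adding events never shrinks the envelope", {
  set.seed(32)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    older <- runif(k, 500, 2000)
    younger <- older - runif(k, 10, 400)
    ev <- data.frame(order = 1:k, donor = letters[1:k],
                     recipient = letters[2:(k + 1)], older = older,
                     younger = younger, feasible = TRUE)
    sub <- scenario_envelope(ev[1:(k - 1), ])
    full <- scenario_envelope(ev)
    expect_gte(full$window$older, sub$window$older)
    expect_lte(full$window$younger, sub$window$younger)
  }
})

# Independent oracle for sequential feasibility: dynamic programme over the
# finite set of candidate event times formed by all window bounds.
seq_oracle <- function(older, younger) {
  if (any(older < younger)) return(FALSE)
  cand <- sort(unique(c(older, younger)), decreasing = TRUE)
  feasible_prev <- cand >= younger[1] & cand <= older[1]
  if (!any(feasible_prev)) return(FALSE)
  for (i in seq_along(older)[-1]) {
    feasible_i <- logical(length(cand))
    for (j in seq_along(cand)) {
      in_win <- cand[j] >= younger[i] && cand[j] <= older[i]
      # needs some feasible previous time >= cand[j]
      feasible_i[j] <- in_win && any(feasible_prev[seq_len(j)])
    }
    if (!any(feasible_i)) return(FALSE)
    feasible_prev <- feasible_i
  }
  TRUE
}

test_that("sequential feasibility agrees with the assignment-enumeration oracle", {
  w <- mcmctree_ac_windows()
  for (sc in c("stiller", "bodyl")) {
    ev <- scenario_windows(scenario_preset(sc), w)
    res <- sequential_feasibility(ev)
    expect_true(res$feasible)
    expect_equal(res$feasible, seq_oracle(ev$older, ev$younger))
  }
  # constructed reversal: event 2 entirely older than event 1
  ev <- data.frame(order = 1:2, donor = c("a", "b"),
                   recipient = c("b", "c"), older = c(900, 1500),
                   younger = c(800, 1000), width = c(100, 500),
                   feasible = c(TRUE, TRUE))
  res <- sequential_feasibility(ev)
  expect_false(res$feasible)
  expect_equal(nrow(res$violations), 1L)
  # randomized chains
  set.seed(33)
  for (i in 1:200) {
    k <- sample(2:5, 1)
    older <- runif(k, 200, 2000)
    younger <- pmax(older - runif(k, 5, 800), 0)
    ev <- data.frame(order = 1:k, donor = letters[1:k],
                     recipient = letters[2:(k + 1)], older = older,
                     younger = younger, width = older - younger,
                     feasible = TRUE)
    expect_equal(sequential_feasibility(ev)$feasible,
                 seq_oracle(older, younger))
  }
})

test_that("lineage windows derive from stem-parent and crown HPDs", {
  # crown (900, 700); stem parent (1200, 1000); root deliberately without
  # an HPD annotation
  txt <- "(((A:800,B:800)[&95%HPD={700,900}]:300,C:1100)[&95%HPD={1000,1200}]:400,D:1500);"
  ch <- chronogram_from_test_text(txt)
  win <- lineage_windows_from_chronogram(ch, list(AB = c("A", "B")))
  expect_equal(win$AB$older, 1200)
  expect_equal(win$AB$younger, 700)
  # single-tip lineage: crown age 0, stem parent HPD older bound
  win2 <- lineage_windows_from_chronogram(ch, list(C = "C"))
  expect_equal(win2$C$older, 1200)
  expect_equal(win2$C$younger, 0)
  expect_error(lineage_windows_from_chronogram(ch, list(AC = c("A", "C"))),
               "not monophyletic")
  expect_error(lineage_windows_from_chronogram(ch, list(ABC = c("A", "B", "C"))),
               "missing HPD")
})

test_that("windows derived from a chronogram reproduce the packaged fixture", {
  # ladder chronogram whose stem-parent/crown HPDs encode the packaged
  # availability windows; each lineage is a 2-tip cherry with its own stem
  # parent node
  path <- system.file("extdata", "lineage_windows_mcmctree_ac.tsv",
                      package = "rhodochron")
  fix <- read_lineage_windows(path)
  p5 <- "((M1:800,M2:800)[&95%HPD={696,1520}]:100,Y:900)[&95%HPD={800,1520}]"
  p4 <- paste0("((H1:700,H2:700)[&95%HPD={579,1943}]:300,", p5,
               ":100)[&95%HPD={900,1943}]")
  p3 <- paste0("((O1:800,O2:800)[&95%HPD={622,1298}]:300,", p4,
               ":100)[&95%HPD={1000,1298}]")
  p2 <- paste0("((C1:1000,C2:1000)[&95%HPD={440,1658}]:500,", p3,
               ":400)[&95%HPD={1400,1658}]")
  p1 <- paste0("((R1:1400,R2:1400)[&95%HPD={1281,1500}]:200,", p2,
               ":100)[&95%HPD={1400,1675}]")
  txt <- paste0("(", p1, ":500,X:2100)[&95%HPD={2000,2200}];")
  ch <- chronogram_from_test_text(txt)
  defs <- list(Rho = c("R1", "R2"), Cry = c("C1", "C2"),
               Och = c("O1", "O2"), Hap = c("H1", "H2"),
               Myz = c("M1", "M2"))
  win <- lineage_windows_from_chronogram(ch, defs)
  for (nm in names(defs)) {
    expect_equal(win[[nm]]$older, fix[[nm]]$older)
    expect_equal(win[[nm]]$younger, fix[[nm]]$younger)
  }
})
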