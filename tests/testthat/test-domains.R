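test_that("the packaged domain config has four entries, three critical", {
  dom <- brca2_domains()
  expect_equal(nrow(dom), 4L)
  expect_equal(sum(dom$critical), 3L)
  expect_equal(attr(dom, "boundary_window"), 5L)
  expect_true(dom$boundary_only[dom$name == "C-terminal region/DBD boundary"])
})

test_that("config validation rejects inverted intervals and duplicate names", {
  expect_error(domain_set(data.frame(name = "x", start = 10L, end = 5L,
                                     critical = TRUE)), "invalid interval")
  expect_error(domain_set(data.frame(name = c("x", "x"),
                                     start = c(1L, 5L), end = c(4L, 9L),
                                     critical = c(TRUE, FALSE))), "duplicate")
  empty <- domain_set(data.frame(name = character(0), start = integer(0),
                                 end = integer(0), critical = logical(0)))
  got <- map_position(c(1L, 500L, 3418L), empty)
  expect_equal(got$category, rep("outside", 3))
})

test_that("positions map onto the annotated BRCA2 regions", {
  dom <- brca2_domains()
  got <- map_position(c(1089L, 2947L, 613L, 3187L, 3079L), dom)
  expect_equal(got$category, c("inside", "inside", "outside", "boundary", "inside"))
  expect_equal(got$domain[1:2], c("BRC repeats", "DNA-binding domain"))
  expect_equal(got$domain[5], "terminal DBD")
  expect_equal(got$distance[4], 2L)  # 3187 sits 2 residues past the terminal DBD
})

test_that("closed-interval edges and the window behave as documented", {
  dom <- brca2_domains()
  expect_equal(map_position(1002L, dom, boundary_window = 0L)$category, "outside")
  expect_equal(map_position(1003L, dom, boundary_window = 0L)$category, "inside")
  expect_equal(map_position(1002L, dom)$category, "boundary")
  # overlap 3052-3054: smallest interval span wins
  expect_equal(map_position(3053L, dom)$domain, "terminal DBD")
})

test_that("enlarging the window never demotes a category", {
  dom <- brca2_domains()
  rank <- c(outside = 0L, boundary = 1L, inside = 2L)
  pos <- 1:3500
  prev <- rank[map_position(pos, dom, boundary_window = 0L)$category]
  for (w in c(2L, 5L, 12L, 30L)) {
    cur <- rank[map_position(pos, dom, boundary_window = w)$category]
    expect_true(all(cur >= prev))
    expect_true(all((prev == 2L) == (cur == 2L)))  # inside never changes
    prev <- cur
  }
})

test_that("assignment over the catalogue matches the published localization", {
  vt <- load_fixture_variants()
  asg <- assign_domains(vt)
  brc <- asg$key[asg$category == "inside" & asg$domain == "BRC repeats"]
  expect_setequal(asg$position[asg$key %in% brc], c(1089L, 1063L, 1161L, 1692L))
  tdb <- asg$position[asg$category == "inside" & asg$domain == "terminal DBD"]
  expect_setequal(tdb, c(3079L, 3122L, 3152L))
  expect_equal(asg$category[asg$position == 3271L], "outside")
  empty <- variant_table(vt$records[0, setdiff(names(vt$records),
                                               c("key", "ref", "position", "alt",
                                                 "consequence"))])
  expect_equal(nrow(assign_domains(empty)), 0L)
})
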