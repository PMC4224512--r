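test_that("target name canonicalization maps the # sigil to *, strips space, is idempotent", {
  expect_equal(normalize_target_name("hsa-miR-106b#"), "hsa-miR-106b*")
  expect_equal(normalize_target_name("mmu-miR-16"), "mmu-miR-16")
  expect_equal(normalize_target_name(" rno-miR-196c "), "rno-miR-196c")
  # species prefixes stay distinct identities
  expect_false(normalize_target_name("hsa-miR-214") ==
                 normalize_target_name("mmu-miR-214"))
  # idempotent on a mixed batch
  raw <- c("hsa-miR-106b#", "mmu-miR-297a#", " mmu-let-7a* ", "rno-miR-1")
  once <- normalize_target_name(raw)
  expect_equal(normalize_target_name(once), once)
  expect_error(normalize_target_name(""), "empty")
})

test_that("long-format reading stores undetected cells and rejects bad input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,target,ct,panel",
               "s1,miR-1,20.5,A", "s1,miR-2,Undetermined,A", "s1,miR-3#,35,B",
               "s2,miR-1,21.5,A", "s2,miR-2,30.25,A", "s2,miR-3#,36,B"), path)
  m <- read_ct_long(path)
  expect_equal(dim(m), c(3L, 2L))
  expect_true(is.na(m$ct["miR-2", "s1"]))
  expect_equal(m$ct["miR-1", "s2"], 21.5)
  expect_equal(rownames(m$ct)[3], "miR-3*")     # canonicalized on load
  expect_equal(unname(m$panel["miR-3*"]), "B")

  writeLines(c("sample,target,ct,panel",
               "sampleA,miR-16,20,A", "sampleA,miR-16,21,A"), path)
  expect_error(read_ct_long(path), "duplicate.*sampleA.*miR-16")

  writeLines(c("sample,target,ct,panel", "s1,miR-1,oops,A"), path)
  expect_error(read_ct_long(path), "unparsable.*line 1")
})

test_that("write followed by read reproduces the cell set bit-exactly", {
  set.seed(42)
  vals <- matrix(runif(12, 14, 39), 4, 3)
  vals[2, 1] <- NA; vals[4, 3] <- NA
  m <- make_ct(vals, panel = c("A", "A", "B", "B"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ct_long(m, path)
  m2 <- read_ct_long(path)
  expect_identical(m2$ct[rownames(m$ct), colnames(m$ct)], m$ct)
  expect_identical(unname(m2$panel[rownames(m$ct)]), unname(m$panel))
})

test_that("reader sniffs tab-delimited metadata and builds a design", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tgroup", "s1\tsham", "s2\tsham", "s3\tIS1", "s4\tIS1"),
             path)
  d <- read_group_design(path, calibrator = "sham")
  expect_s3_class(d, "group_design")
  expect_equal(unname(d$assignment[c("s3", "s4")]), c("IS1", "IS1"))
  expect_error(read_group_design(path, calibrator = "nope"), "calibrator")
})

test_that("panel merging unions disjoint targets and is symmetric in content", {
  a <- make_ct(matrix(20, 3, 6), targets = paste0("a", 1:3), panel = "A")
  b <- make_ct(matrix(25, 4, 6), targets = paste0("b", 1:4), panel = "B")
  m <- merge_panels(a, b)
  expect_equal(nrow(m$ct), 7L)
  expect_equal(unname(m$panel), rep(c("A", "B"), c(3, 4)))

  m2 <- merge_panels(b, a)
  long1 <- withr::local_tempfile(); long2 <- withr::local_tempfile()
  write_ct_long(m, long1); write_ct_long(m2, long2)
  df1 <- read.csv(long1); df2 <- read.csv(long2)
  key <- function(d) d[order(d$sample, d$target), c("sample", "target", "ct")]
  expect_equal(key(df1), key(df2), ignore_attr = TRUE)

  b_short <- make_ct(matrix(25, 4, 5), targets = paste0("b", 1:4))
  expect_error(merge_panels(a, b_short), "sample sets differ.*s6")
  a2 <- make_ct(matrix(20, 1, 6), targets = "b2")
  expect_error(merge_panels(a2, b), "both panels: b2")
})
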