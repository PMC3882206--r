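test_that("expression matrix round trip through TSV is bit-exact", {
  set.seed(42)
  m <- matrix(rnorm(30) * 10^sample(-3:3, 30, TRUE), 6, 5,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:5)))
  em <- expression_matrix(m, namespace = "ensembl")
  f <- tempfile(fileext = ".tsv")
  write_expression_matrix(em, f)
  back <- read_expression_matrix(f, namespace = "ensembl")
  expect_identical(unclass(back)[, ], unclass(em)[, ])
  expect_identical(attr(back, "namespace"), "ensembl")
})

test_that("expression matrix reader validates its input", {
  f <- tiny_expression_file()
  em <- read_expression_matrix(f)
  expect_equal(dim(em), c(3L, 2L))
  expect_equal(rownames(em), c("g1", "g2", "g3"))
  expect_equal(unclass(em)["g2", "s2"], -1.25)

  dup <- tempfile(); writeLines(c("gene_id\ts1", "g1\t1", "g1\t2"), dup)
  expect_error(read_expression_matrix(dup), "duplicate gene id")

  blank <- tempfile(); writeLines(c("gene_id\ts1\ts2", "g1\t1\t"), blank)
  expect_error(read_expression_matrix(blank), "non-numeric value")

  txt <- tempfile(); writeLines(c("gene_id\ts1", "g1\tabc"), txt)
  expect_error(read_expression_matrix(txt), "non-numeric value")

  # comma-separated input is auto-detected
  csv <- tempfile(); writeLines(c("gene_id,s1,s2", "g1,1,2"), csv)
  expect_equal(unclass(read_expression_matrix(csv))[1, ], c(s1 = 1, s2 = 2))
})

test_that("sample table reader enforces the metadata contract", {
  st <- read_sample_table(tiny_sample_file())
  expect_s3_class(st, "SampleTable")
  expect_equal(nrow(st), 4)
  expect_equal(sort(unique(st$group)), c("AL", "CR"))

  nog <- tempfile(); writeLines(c("sample_id\tdataset_id\ttissue", "s1\tC1\tliver"), nog)
  expect_error(read_sample_table(nog), "missing required column")

  neg <- tempfile()
  writeLines(c("sample_id\tdataset_id\ttissue\tgroup\tage", "s1\tC1\tliver\tCR\t-1"), neg)
  expect_error(read_sample_table(neg), "negative age")

  dup <- tempfile()
  writeLines(c("sample_id\tdataset_id\ttissue\tgroup",
               "s1\tC1\tliver\tCR", "s1\tC1\tliver\tAL"), dup)
  expect_error(read_sample_table(dup), "duplicate sample_id")

  odd <- tempfile()
  writeLines(c("sample_id\tdataset_id\ttissue\tgroup", "s1\tC1\tkidney\tCR"), odd)
  expect_warning(st2 <- read_sample_table(odd), "other")
  expect_equal(st2$tissue, "other")
})

test_that("GMT reader deduplicates members and rejects short lines", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("SET1\tdesc\tg1\tg2\tg3\tg4\tg5\tg6",
               "SET2\tdesc\tg1\tg1\tg2"), f)
  gs <- read_gene_sets(f)
  expect_length(gs, 2)
  expect_equal(lengths(gs), c(SET1 = 6L, SET2 = 2L))

  bad <- tempfile(); writeLines(c("SET1\tdesc\tg1", "SETX\tonly2fields"), bad)
  expect_error(read_gene_sets(bad), "fewer than 3 fields")

  empty <- tempfile(); writeLines(c("SET1\tdesc\tg1", "SET2\tdesc\t "), empty)
  expect_warning(gs2 <- read_gene_sets(empty), "empty")
  expect_length(gs2, 1)
})

test_that("ortholog mapping restricts, renames, sorts and is idempotent on identity", {
  m <- expression_matrix(matrix(1:10, 5, 2,
                                dimnames = list(paste0("m", 5:1), c("s1", "s2"))),
                         namespace = "mouse")
  ident <- data.frame(source = paste0("m", 1:5), target = paste0("m", 1:5))
  out <- map_orthologs(m, ident, target_namespace = "mouse")
  expect_equal(rownames(out), sort(rownames(m)))
  expect_equal(unclass(out)["m3", ], unclass(m)["m3", ])
  out2 <- map_orthologs(out, ident, target_namespace = "mouse")
  expect_equal(unclass(out2)[, ], unclass(out)[, ])

  partial <- data.frame(source = c("m1", "m3", "m5"), target = c("h1", "h3", "h5"))
  mapped <- map_orthologs(m, partial, target_namespace = "human")
  expect_equal(nrow(mapped), 3)
  expect_equal(attr(mapped, "mapping_report")$n_dropped, 2)
  expect_equal(rownames(mapped), c("h1", "h3", "h5"))

  dup <- data.frame(source = c("m1", "m2"), target = c("h1", "h1"))
  expect_error(map_orthologs(m, dup), "one-to-one")
  expect_error(validate_ortholog_map(
    data.frame(source = c("a", "a"), target = c("x", "y"))), "one-to-one")
})

test_that("ortholog map file reader handles optional header", {
  f <- tempfile()
  writeLines(c("source\ttarget", "m1\th1", "m2\th2"), f)
  expect_equal(nrow(read_ortholog_map(f)), 2)
  f2 <- tempfile()
  writeLines(c("m1\th1", "m2\th2", "m3\th3"), f2)
  expect_equal(read_ortholog_map(f2)$target, c("h1", "h2", "h3"))
})

test_that("stage config enforces contiguous windows and exposes defaults", {
  cfg <- species_stage_config()
  expect_equal(cfg$human$development, c(0, 20))
  expect_equal(cfg$chimpanzee$aging, c(12, 54))
  expect_equal(cfg$macaque$development, c(0, 6))
  expect_equal(cfg$human$conception_offset_days, 280)
  expect_equal(cfg$mouse$conception_offset_days, 19)
  expect_error(species_stage_config(list(
    human = list(development = c(0, 20), aging = c(25, 98),
                 conception_offset_days = 280))),
    "development must end where aging begins")
  expect_error(species_stage_config(list(
    human = list(development = c(5, 5), aging = c(5, 98),
                 conception_offset_days = 280))),
    "empty stage interval")
})
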