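# Trait curation: aggregation rules, sporulation imputation, categorical
# encodings, and mapping taxon-level data onto tree tips.

test_that("aggregation uses mean for continuous and mode for discrete traits", {
  rec <- data.frame(
    taxon = c("Escherichia coli", "Escherichia coli",
              "Escherichia coli", "Escherichia coli", "Escherichia coli",
              "Bacteroides fragilis"),
    trait = c("temperature_optimum", "temperature_optimum",
              "oxygen_tolerance", "oxygen_tolerance", "oxygen_tolerance",
              "genome_size"),
    value = c(2, 4, 1, 1, 0, 5.2))
  tt <- aggregate_records(rec)
  expect_equal(tt$values["Escherichia coli", "temperature_optimum"], 3)
  expect_equal(tt$values["Escherichia coli", "oxygen_tolerance"], 1) # mode
  expect_equal(tt$values["Bacteroides fragilis", "genome_size"], 5.2)
  expect_identical(tt$provenance["Bacteroides fragilis", "genome_size"],
                   "observed")
  expect_identical(tt$provenance["Bacteroides fragilis", "motility"],
                   "missing")

  # mode ties average the tied values, keeping scores in range
  tie <- data.frame(taxon = "X y", trait = "gram_positive",
                    value = c(0, 0, 1, 1))
  expect_equal(aggregate_records(tie)$values[1, "gram_positive"], 0.5)

  # sizes are log-transformed from raw micrometres
  sz <- data.frame(taxon = "X y", trait = "length", value = c(2, 8))
  expect_equal(aggregate_records(sz)$values[1, "length"], mean(log(c(2, 8))))

  expect_error(aggregate_records(data.frame(taxon = "a b", trait = "sp00",
                                            value = 1)), "schema-error")
  expect_error(aggregate_records(data.frame(taxon = "a b", trait = "length",
                                            value = "big")), "parse-error")
})

test_that("aggregation is permutation-invariant and idempotent in spirit", {
  set.seed(41)
  rec <- data.frame(taxon = sample(c("A a", "B b"), 30, TRUE),
                    trait = sample(c("gc_content", "oxygen_tolerance"), 30, TRUE),
                    value = sample(0:5, 30, TRUE))
  t1 <- aggregate_records(rec)
  t2 <- aggregate_records(rec[sample(nrow(rec)), ])
  expect_identical(t1$values, t2$values)
})

test_that("sporulation imputation follows the quantitative-median rule", {
  expect_equal(impute_sporulation("spores_present"), 0.549)
  expect_equal(impute_sporulation("spores_absent"), 0)
  expect_equal(impute_sporulation(0.8), 0.8)           # quantitative wins
  expect_equal(impute_sporulation(c("0.8", "spores_present")), c(0.8, 0.549))
  expect_error(impute_sporulation("maybe"), "vocabulary-error")
})

test_that("categorical encodings match the documented scales", {
  expect_equal(encode_discrete("gram_positive", "positive"), 1)
  expect_equal(encode_discrete("gram_positive", "negative"), 0)
  expect_equal(encode_discrete("oxygen_tolerance", "obligate anaerobe"), 0)
  expect_equal(encode_discrete("oxygen_tolerance", "obligate aerobe"), 5)
  expect_equal(encode_discrete("motility", "sometimes motile"), 0.5)
  expect_error(encode_discrete("motility", "wiggly"), "vocabulary-error")
  expect_error(encode_discrete("genome_size", "big"), "vocabulary-error")

  # encodings stay inside the vocabulary bounds
  voc <- trait_vocabulary()
  for (tr in c("gram_positive", "motility", "oxygen_tolerance")) {
    rng <- voc[voc$trait == tr, c("lower", "upper")]
    vals <- traitsuccession:::.discrete_vocab[[tr]]
    expect_true(all(vals >= rng$lower & vals <= rng$upper))
  }
})

test_that("taxon traits map onto tree tips through the name map", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  tab <- trait_table(matrix(c(37, 42), 2, 1,
                            dimnames = list(c("Escherichia coli", "Vibrio sp"),
                                            "temperature_optimum")))
  empty <- map_traits_to_tree(tr, tab, data.frame(tip = character(),
                                                  taxon = character()))
  expect_true(all(is.na(empty$values)))

  one <- map_traits_to_tree(tr, tab,
                            data.frame(tip = "B", taxon = "Escherichia coli"))
  expect_equal(one$values["B", 1], 37)
  expect_true(all(is.na(one$values[c("A", "C", "D"), ])))
  expect_equal(unname(attr(one, "match_count")), 1L)

  # consistency with the masking generator: matched count == mask count
  big <- simulate_tree(100, 0.3, seed = 42)
  x <- simulate_continuous_trait(big, 1, seed = 43)
  m <- mask_traits(x, 0.5, seed = 44)
  tab2 <- trait_table(matrix(x[m], ncol = 1,
                             dimnames = list(names(x)[m], "gc_content")))
  nm <- data.frame(tip = names(x)[m], taxon = names(x)[m])
  mapped <- map_traits_to_tree(big, tab2, nm)
  expect_equal(unname(attr(mapped, "match_count")), sum(m))
})

test_that("trait tables validate provenance and report composition", {
  v <- matrix(c(1, NA), 2, 1, dimnames = list(c("t1", "t2"), "gc_content"))
  tt <- trait_table(v)
  expect_identical(tt$provenance[, 1], c(t1 = "observed", t2 = "missing"))
  expect_error(trait_table(v, provenance = matrix("guessed", 2, 1)),
               "provenance")
})
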