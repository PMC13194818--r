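test_that("extract_identifier finds rs numbers and HGVS notations", {
  id <- extract_identifier("What is the clinical significance of rs34637584 in ClinVar?")
  expect_s3_class(id, "variant_identifier")
  expect_equal(id$kind, "rs")
  expect_equal(id$raw, "rs34637584")

  expect_null(extract_identifier("Tell me about Parkinson disease."))

  hg <- extract_identifier("Interpret ENST00000298910.12:c.6055G>A please")
  expect_equal(hg$kind, "hgvs")
  expect_equal(hg$raw, "ENST00000298910.12:c.6055G>A")
})

test_that("rs detection is case-insensitive, word-bounded and deduplicating", {
  expect_equal(extract_identifier("Tell me about RS671.")$raw, "rs671")
  # repeated identical mentions collapse
  expect_equal(
    extract_identifier("Is rs671 (also written RS671) common? rs671 again.")$raw,
    "rs671"
  )
  # 'rs' embedded in a word is not an identifier
  expect_null(extract_identifier("The answers123 dataset is unrelated."))
})

test_that("distinct identifiers raise ambiguity errors; rs wins over HGVS", {
  expect_error(
    extract_identifier("Compare rs671 with rs34637584."),
    class = "ragvar_ambiguity_error"
  )
  expect_error(
    extract_identifier("Is NM_1.1:c.1A>T the same as NM_2.1:c.2A>T?"),
    class = "ragvar_ambiguity_error"
  )
  both <- extract_identifier("Is rs34637584 identical to ENST00000298910.12:c.6055G>A?")
  expect_equal(both$kind, "rs")
})

test_that("extraction is idempotent on its own match", {
  questions <- c(
    "Could you show me the allele frequency of rs699 in Japanese populations?",
    "Interpret chr12:g.40340400G>A for me",
    "What about ENSP00000298910.7:p.Gly2019Ser?"
  )
  for (q in questions) {
    id <- extract_identifier(q)
    again <- extract_identifier(id$raw)
    expect_equal(again$kind, id$kind)
    expect_equal(again$raw, id$raw)
  }
})

test_that("parse_genomic_hgvs handles the genomic SNV grammar only", {
  al <- parse_genomic_hgvs("chr12:g.40340400G>A")
  expect_s3_class(al, "genomic_allele")
  expect_equal(al$chromosome, "12")
  expect_equal(al$position, 40340400L)
  expect_equal(al$ref, "G")
  expect_equal(al$alt, "A")

  expect_null(parse_genomic_hgvs("ENSP00000298910.7:p.Gly2019Ser"))
  expect_null(parse_genomic_hgvs("ENST00000298910.12:c.6055G>A"))
  expect_null(parse_genomic_hgvs("NC_000012.12:g.40340400G>A"))
  expect_null(parse_genomic_hgvs("chr1:g.5AT>GC"))  # not an SNV

  expect_error(parse_genomic_hgvs("chr12:g.0G>A"), class = "ragvar_parse_error")
  expect_error(parse_genomic_hgvs("chr12:g.100G>G"), class = "ragvar_parse_error")
  expect_error(parse_genomic_hgvs("chr99:g.100G>A"), class = "ragvar_parse_error")
})

test_that("render and parse are inverse on the accepted grammar", {
  withr::with_seed(42, {
    for (i in 1:50) {
      chrom <- sample(c(as.character(1:22), "X", "Y", "MT"), 1)
      pos <- sample.int(2.4e8, 1)
      ref <- sample(c("A", "C", "G", "T"), 1)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      s <- sprintf("chr%s:g.%d%s>%s", chrom, pos, ref, alt)
      expect_identical(render_genomic_hgvs(parse_genomic_hgvs(s)), s)
    }
  })
})

test_that("genomic_allele enforces its invariants", {
  expect_error(genomic_allele("12", 10, "G", "G"), class = "ragvar_parse_error")
  expect_error(genomic_allele("12", 0, "G", "A"), class = "ragvar_parse_error")
  expect_error(genomic_allele("banana", 1, "G", "A"), class = "ragvar_parse_error")
  expect_error(genomic_allele("12", 10, "", "A"), class = "ragvar_parse_error")
  # chr prefix is normalized away
  expect_equal(genomic_allele("chrX", 5, "t", "c")$chromosome, "X")
})

test_that("normalize_identifier routes rs, local genomic, and recoder paths", {
  rec <- packaged_recoder()

  expect_identical(
    normalize_identifier(variant_identifier("rs", "rs34637584"), rec),
    "rs34637584"
  )

  # transcript-level HGVS goes through the recoder lookup
  al <- normalize_identifier(
    variant_identifier("hgvs", "ENST00000298910.12:c.6055G>A"), rec
  )
  expect_equal(al$chromosome, "12")
  expect_equal(al$position, 40340400L)
  expect_equal(al$ref, "G")
  expect_equal(al$alt, "A")

  # genomic-level SNV needs no recoder at all
  expect_s3_class(
    normalize_identifier(variant_identifier("hgvs", "chr12:g.40340400G>A"),
                         recoder = NULL),
    "genomic_allele"
  )

  expect_error(
    normalize_identifier(variant_identifier("hgvs", "NM_000000.0:c.1A>T"),
                         fixture_recoder()),
    class = "ragvar_unresolvable_error"
  )

  multi <- fixture_recoder(list("NM_1.1:c.5A>T" = c("1:100:A:T", "1:200:A:T")))
  err <- tryCatch(
    normalize_identifier(variant_identifier("hgvs", "NM_1.1:c.5A>T"), multi),
    condition = function(e) e
  )
  expect_s3_class(err, "ragvar_ambiguity_error")
  expect_length(err$candidates, 2)
})
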