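test_that("amplicon_span does inclusive primer arithmetic", {
  win <- amplicon_span("F15,386", "R16,330")
  expect_equal(win$start, 15386)
  expect_equal(win$end, 16330)
  expect_equal(win$L, 945)

  ## the control region proper, 15,400..16,146
  expect_equal(amplicon_span("F15,400", "R16,146")$L, 747)

  expect_equal(parse_primer_position("R16,330"), 16330)
  expect_equal(parse_primer_position("15386"), 15386)
  expect_error(parse_primer_position("FX"), "parse")
  expect_error(amplicon_span("F100", "R10"), "exceed")
  expect_error(amplicon_span("F10", "R10"), "exceed")
})

test_that("map_to_reference places identical, mutated and fragment input", {
  ref <- generate_reference(945, origin = 15386, seed = 21)
  full <- substring(ref$sequence, 1, 945)

  m <- map_to_reference(full, ref)
  expect_equal(c(m$start, m$end, m$mismatches), c(15386, 16330, 0))

  ## one substitution: same placement, one mismatch recorded
  mut <- seq_chars(full)
  mut[500] <- setdiff(c("A", "C", "G", "T"), mut[500])[1]
  m1 <- map_to_reference(paste(mut, collapse = ""), ref)
  expect_equal(c(m1$start, m1$mismatches), c(15386, 1))

  ## 450-base fragment lands at the correct offset
  frag <- substring(ref$sequence, 301, 750)
  mf <- map_to_reference(frag, ref)
  expect_equal(c(mf$start, mf$end), c(15386 + 300, 15386 + 749))
  expect_equal(mf$end - mf$start + 1L, 450)

  ## indels are a named hard error, not a silent gap
  expect_error(map_to_reference(paste0(substring(full, 1, 99), "-",
                                       substring(full, 101, 945)), ref),
               "position 100")
  ## garbage that matches nowhere is unmappable
  expect_error(
    map_to_reference(strrep("ACGT", 50), generate_reference(945, seed = 99)),
    "unmappable"
  )
  ## ambiguity codes carry no mismatch evidence
  amb <- seq_chars(full)
  amb[200:210] <- "N"
  ma <- map_to_reference(paste(amb, collapse = ""), ref)
  expect_equal(ma$mismatches, 0)
  expect_equal(ma$compared, 945 - 11)
})

test_that("segregating sites match a direct column-scan oracle", {
  pos <- hap_global$positioned
  seg <- call_segregating_sites(pos)
  expect_equal(length(seg), 6)

  ## direct scan oracle over every window position
  ref <- fx_global$reference
  for (p in seq(15386, 16330, by = 97)) {
    bases <- vapply(pos, function(r) {
      if (p < r$start || p > r$end) NA_character_
      else substring(r$seq, p - r$start + 1L, p - r$start + 1L)
    }, character(1))
    bases <- bases[!is.na(bases) & bases %in% c("A", "C", "G", "T")]
    expect_equal(p %in% seg, length(unique(bases)) >= 2, info = p)
  }
  for (p in seg) { # every reported site verified by the same scan
    bases <- vapply(pos, function(r)
      substring(r$seq, p - r$start + 1L, p - r$start + 1L), character(1))
    expect_gte(length(unique(bases[bases %in% c("A", "C", "G", "T")])), 2)
  }

  ## all-identical input has none; empty input errors
  two <- structure(pos[c(1, 1)], class = "positioned_seqs")
  expect_equal(length(call_segregating_sites(two)), 0)
  expect_error(call_segregating_sites(list()), "no sequences")
})

test_that("regional subsets segregate at the published per-region S", {
  st <- stats_table(hap_regional$positioned, hap_regional$assignments,
                    fx_regional$metadata, hap_regional$registry)
  S <- setNames(st$S, st$region)
  expect_equal(as.list(S[c("NW", "NM", "NE", "SW", "SM", "SE", "Overall")]),
               list(NW = 1L, NM = 2L, NE = 2L, SW = 3L, SM = 2L, SE = 4L,
                    Overall = 6L))
})

test_that("haplotype collapsing is exact, order-invariant and idempotent", {
  asn <- hap_global$assignments
  expect_equal(length(unique(asn$haplotype)), 6)
  expect_false(anyNA(asn$haplotype))

  ## input order must not change the partition
  perm <- rev(hap_global$positioned)
  asn_perm <- assign_haplotypes(structure(perm, class = "positioned_seqs"),
                                fx_global$registry,
                                fx_global$reference)$assignments
  expect_identical(asn_perm, asn)

  ## idempotent, registry unchanged (monotone growth, no renames)
  again <- assign_haplotypes(hap_global$positioned, hap_global$registry,
                             fx_global$reference)
  expect_identical(again$assignments, asn)
  expect_identical(again$registry$haplotypes, hap_global$registry$haplotypes)
})

test_that("novel full-coverage vectors register sequential names", {
  fx <- fx_regional
  ## invent a sequence carrying a substitution at a fresh position
  novel <- seq_chars(fx$sequences[[1]])
  idx <- 16100 - 15386 + 1
  novel[idx] <- setdiff(c("A", "C", "G", "T"), novel[idx])[1]
  seqs <- c(fx$sequences[1:3], novel_1 = paste(novel, collapse = ""))
  pos <- map_sequences(seqs, fx$reference)

  expect_error(
    assign_haplotypes(pos, fx$registry, fx$reference, allow_new = FALSE),
    "allow_new"
  )
  res <- assign_haplotypes(pos, fx$registry, fx$reference, allow_new = TRUE)
  expect_equal(names(res$registry$haplotypes),
               c(paste0("Hun", 1:6), "Hun7"))
  expect_equal(res$registry$haplotypes$Hun7,
               setNames(novel[idx], "16100"))
  expect_equal(res$assignments$haplotype[res$assignments$sample_id == "novel_1"],
               "Hun7")
  ## prior entries untouched
  expect_identical(res$registry$haplotypes[paste0("Hun", 1:6)],
                   fx$registry$haplotypes)
})

test_that("partial fragments constrain rather than assign", {
  fx <- fx_regional
  ## fragment covering no variable site: consistency set = every haplotype
  ## (placed before the first variable site, so no discriminating evidence)
  rec <- list(id = "blank", seq = substring(fx$sequences[[1]], 1, 100),
              start = 15386, end = 15485)
  res <- assign_haplotypes(structure(list(rec), class = "positioned_seqs"),
                           fx$registry, fx$reference)
  expect_true(is.na(res$assignments$haplotype[1]))
  expect_equal(strsplit(res$assignments$consistent_with[1], ",")[[1]],
               paste0("Hun", 1:6))

  ## a fragment's consistency set always contains its source haplotype
  h <- run_haplotyping(fx)
  src <- setNames(h$assignments$haplotype, h$assignments$sample_id)
  frags <- fragment_samples(fx$sequences[seq(1, 192, by = 13)], 150, 600,
                            seed = 9)
  fres <- assign_haplotypes(frags, fx$registry, fx$reference)$assignments
  for (i in seq_len(nrow(fres))) {
    consist <- strsplit(fres$consistent_with[i], ",")[[1]]
    expect_true(src[[fres$sample_id[i]]] %in% consist,
                info = fres$sample_id[i])
  }
})

test_that("haplotype_frequencies tabulates counts and reports exclusions", {
  tab <- hap_global$pop_table
  expect_equal(unname(rowSums(tab)[c("NW", "NM", "NE", "SW", "SM", "SE")]),
               c(34, 42, 41, 37, 31, 7))

  ## proportions from a tiny hand table
  asn <- data.frame(
    sample_id = c("a", "b", "c", "d"),
    haplotype = c("H1", "H1", "H1", "H2"),
    stringsAsFactors = FALSE
  )
  md <- data.frame(sample_id = c("a", "b", "c", "d"), region = "X",
                   stringsAsFactors = FALSE)
  t1 <- haplotype_frequencies(asn, md)
  expect_equal(unname(t1["X", ] / sum(t1["X", ])), c(0.75, 0.25))

  ## unassigned samples are excluded and reported
  asn$haplotype[2] <- NA
  t2 <- haplotype_frequencies(asn, md)
  expect_equal(sum(t2), 3)
  expect_equal(attr(t2, "excluded"), "b")

  ## a sample without a region label is an error
  expect_error(haplotype_frequencies(asn, md[-1, , drop = FALSE]),
               "region label")
})
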