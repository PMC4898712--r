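# Engineer a reference around known primer-site content: random flanks with
# controlled site sequences at known offsets.
build_ref_with_sites <- function(fwd_site, rev_site_rc, flank = 120, seed = 1) {
  withr::with_seed(seed, {
    paste0(random_dna(flank), fwd_site, random_dna(260), rev_site_rc,
           random_dna(flank))
  })
}

mutate_site <- function(site, n_mismatch, seed = 1) {
  withr::with_seed(seed, {
    chars <- strsplit(site, "")[[1]]
    pos <- sample(length(chars), n_mismatch)
    chars[pos] <- vapply(chars[pos],
                         function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                         character(1))
    paste(chars, collapse = "")
  })
}

test_that("reverse complement applies IUPAC mapping and is an involution", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("ATTACCGCGGCTGCTGG"), "CCAGCAGCCGCGGTAAT")
  expect_equal(reverse_complement("A"), "T")
  expect_equal(reverse_complement("RYSWKM"), "KMWSRY")
  expect_error(reverse_complement("ACGZ"), "invalid")
  withr::with_seed(31, {
    for (rep in 1:20) {
      s <- random_dna(sample(5:80, 1))
      expect_equal(reverse_complement(reverse_complement(s)), s)
    }
  })
})

test_that("primer windows are located at exact and mismatched sites", {
  primers <- universal_v1v3_primers()
  fwd <- primers$sequence[primers$name == "63f"]      # length 18
  rev_rc <- reverse_complement(primers$sequence[primers$name == "518r"])

  withr::with_seed(41, {
    ref <- tibble::tibble(
      ref_id = "R",
      sequence = paste0(random_dna(20), fwd, random_dna(200), rev_rc,
                        random_dna(30))
    )
  })
  win <- locate_primer_windows(ref, primers, max_mismatches = 0)
  w63 <- win[win$primer == "63f", ]
  expect_equal(c(w63$start, w63$end), c(20L, 38L))
  expect_equal(w63$mismatches, 0L)
  w518 <- win[win$primer == "518r", ]
  expect_equal(c(w518$start, w518$end), c(238L, 255L))

  # primer at offset 0
  ref0 <- tibble::tibble(ref_id = "R0",
                         sequence = paste0(fwd, strrep("T", 60)))
  w <- locate_primer_windows(ref0, primers[1, ], max_mismatches = 0)
  expect_equal(c(w$start, w$end), c(0L, 18L))

  # absent beyond the cap: no window row
  withr::with_seed(42, {
    refx <- tibble::tibble(ref_id = "X", sequence = random_dna(300))
  })
  expect_equal(nrow(locate_primer_windows(refx, primers[1, ],
                                          max_mismatches = 0)), 0)
})

test_that("IUPAC primer codes cover template bases when locating windows", {
  primers <- primer_spec("amb", "ACGTRYN", "forward")
  ref <- tibble::tibble(ref_id = "R",
                        sequence = paste0(strrep("T", 12), "ACGTGCA",
                                          strrep("T", 12)))
  # R covers G, Y covers C, N covers A: exact IUPAC match
  w <- locate_primer_windows(ref, primers, max_mismatches = 0)
  expect_equal(w$mismatches, 0L)
  expect_equal(c(w$start, w$end), c(12L, 19L))
})

test_that("per-read audits count substitutions and indels inside the window", {
  primers <- universal_v1v3_primers()[1, ]
  fwd <- primers$sequence
  withr::with_seed(43, {
    ref <- tibble::tibble(
      ref_id = "R", sequence = paste0(random_dna(60), fwd, random_dna(120))
    )
  })
  win <- locate_primer_windows(ref, primers, max_mismatches = 0)

  # perfect fragment spanning the site: (0,0,0)
  q <- substr(ref$sequence, 31, 140)
  rep0 <- audit_read(align_pair(q, ref$sequence), win)
  expect_true(rep0$site_covered)
  expect_equal(c(rep0$mismatches, rep0$insertions, rep0$deletions),
               c(0L, 0L, 0L))

  # three substitutions inside the window (window is ref [60, 78))
  qc <- strsplit(q, "")[[1]]
  for (p in c(35, 40, 44)) {  # ref positions 64, 69, 73
    qc[p] <- setdiff(c("A", "C", "G", "T"), qc[p])[1]
  }
  rep3 <- audit_read(align_pair(paste(qc, collapse = ""), ref$sequence), win)
  expect_equal(c(rep3$mismatches, rep3$insertions, rep3$deletions),
               c(3L, 0L, 0L))

  # one base missing inside the window
  rep_del <- audit_read(align_pair(paste(strsplit(q, "")[[1]][-40], collapse = ""),
                                   ref$sequence), win)
  expect_equal(c(rep_del$mismatches, rep_del$insertions, rep_del$deletions),
               c(0L, 0L, 1L))

  # one extra base inside the window
  rep_ins <- audit_read(align_pair(paste(append(strsplit(q, "")[[1]], "A", after = 40),
                                         collapse = ""),
                                   ref$sequence), win)
  expect_equal(rep_ins$insertions, 1L)

  # fragment stopping short of the site: not covered, zero counts
  short <- audit_read(align_pair(substr(ref$sequence, 1, 50), ref$sequence), win)
  expect_false(short$site_covered)
  expect_equal(short$mismatches + short$insertions + short$deletions, 0L)
})

test_that("references carrying divergent primer sites yield per-read mismatch counts", {
  # A taxon whose rRNA differs from the universal primers: six substitutions
  # engineered into the forward site, two into the reverse site. Error-free
  # fragments spanning a site must report exactly those counts.
  primers <- universal_v1v3_primers()
  fwd <- primers$sequence[1]
  rev_rc <- reverse_complement(primers$sequence[2])
  fwd_mut <- mutate_site(fwd, 6, seed = 51)
  rev_mut <- mutate_site(rev_rc, 2, seed = 52)
  ref <- tibble::tibble(
    ref_id = "spiro",
    sequence = build_ref_with_sites(fwd_mut, rev_mut, seed = 53)
  )
  win <- locate_primer_windows(ref, primers, max_mismatches = 6)
  expect_equal(sort(win$mismatches), c(2L, 6L))

  # an error-free fragment spanning both sites
  q <- substr(ref$sequence, 101, 560)
  rep <- audit_read(align_pair(q, ref$sequence), win)
  expect_equal(rep$mismatches[rep$primer == "63f"], 6L)
  expect_equal(rep$mismatches[rep$primer == "518r"], 2L)
  expect_equal(sum(rep$insertions) + sum(rep$deletions), 0L)
})

test_that("taxon roll-ups compute both ratio orientations", {
  reports <- tibble::tibble(
    id = sprintf("r%02d", 1:14),
    ref_id = "R",
    primer = "63f",
    site_covered = c(rep(TRUE, 10), rep(TRUE, 4)),
    mismatches = c(rep(0L, 5), rep(1L, 5), rep(2L, 4)),
    insertions = 0L,
    deletions = 0L
  )
  ass <- tibble::tibble(
    id = reports$id,
    phylum = c(rep("Spirochaetes", 10), rep("Firmicutes", 4))
  )
  out <- taxon_mismatch_ratio(reports, ass, rank = "phylum")
  spi <- out[out$taxon == "Spirochaetes", ]
  # 10 reads with site, 5 events -> reads-per-event ratio 2.0
  expect_equal(spi$reads_with_site, 10L)
  expect_equal(spi$total_events, 5)
  expect_equal(spi$ratio_reads_per_event, 2.0)
  expect_equal(spi$ratio_events_per_read, 1.0)
  fir <- out[out$taxon == "Firmicutes", ]
  # 4 reads, 8 events -> 0.5
  expect_equal(fir$ratio_reads_per_event, 0.5)

  # zero events: ratio not applicable
  none <- taxon_mismatch_ratio(
    dplyr::mutate(reports, mismatches = 0L), ass, "phylum"
  )
  expect_true(all(is.na(none$ratio_reads_per_event)))
})
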