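test_that("locate_cdr selects exactly the residues in the numbering range", {
  ch <- make_chain(120, "H", "heavy")
  spec <- locate_cdr(ch, "HCDR3")  # chothia range 95..102
  expect_equal(spec$start_idx, 95L)
  expect_equal(spec$end_idx, 102L)
  expect_equal(spec$end_idx - spec$start_idx + 1L, 8L)
  expect_equal(spec$shift, c(0L, 0L))
})

test_that("insertion-coded residues inside the range grow the window", {
  sp <- toy_spec(n_complexes = 1, len_range = c(10L, 10L),
                 n_loop_classes = 1L, seed = 2)
  cx <- make_toy_complex(sp, 1)
  spec <- locate_cdr(cx$chains$H, "HCDR3")
  # manual enumeration: 10 loop residues numbered 95..100,100A,100B,101,102
  expect_equal(spec$end_idx - spec$start_idx + 1L, 10L)
  nums <- cx$chains$H$residues$res_number[spec$start_idx:spec$end_idx]
  expect_true(all(nums >= 95 & nums <= 102))
})

test_that("role-incompatible or absent CDRs raise errors", {
  ch <- make_chain(120, "H", "heavy")
  expect_error(locate_cdr(ch, "LCDR1"), "heavy")
  short <- make_chain(10, "H", "heavy", start_num = 200L)
  expect_error(locate_cdr(short, "HCDR3"), "range")
  # CDR at the chain terminus lacks an anchor
  term <- make_chain(8, "H", "heavy", start_num = 95L)
  expect_error(locate_cdr(term, "HCDR3"), "anchor")
})

test_that("anchor augmentation enumerates (2k+1)^2 interior variants", {
  base <- cdr_spec("H", "HCDR3", 50L, 57L)
  vars <- augment_anchors(base, k = 3L, chain_len = 120L)
  expect_length(vars, 49L)
  expect_length(augment_anchors(base, k = 0L, chain_len = 120L), 1L)
  v0 <- augment_anchors(base, k = 0L, chain_len = 120L)[[1]]
  expect_equal(v0$start_idx, base$start_idx)
  expect_equal(v0$end_idx, base$end_idx)

  # window arithmetic and duplicate-freedom
  shifts <- t(vapply(vars, `[[`, integer(2), "shift"))
  expect_false(anyDuplicated(shifts) > 0)
  for (v in vars) {
    expect_equal(v$start_idx, base$start_idx + v$shift[1])
    expect_equal(v$end_idx, base$end_idx + v$shift[2])
  }
})

test_that("clamped augmentation matches a brute-force enumeration oracle", {
  for (case in list(list(s = 2L, e = 6L, k = 5L, L = 30L),
                    list(s = 3L, e = 9L, k = 4L, L = 11L),
                    list(s = 10L, e = 12L, k = 2L, L = 13L))) {
    base <- cdr_spec("H", "HCDR3", case$s, case$e)
    got <- augment_anchors(base, case$k, case$L)
    # independent double-loop oracle over all (2k+1)^2 shift pairs
    cnt <- 0L
    for (ds in -case$k:case$k) for (de in -case$k:case$k) {
      s2 <- case$s + ds; e2 <- case$e + de
      if (s2 <= e2 && s2 - 1L >= 1L && e2 + 1L <= case$L) cnt <- cnt + 1L
    }
    expect_length(got, cnt)
    expect_lte(length(got), (2L * case$k + 1L)^2)
  }
})

test_that("cdr_sequence slices the chain sequence exactly", {
  aa <- c("Q", "V", "K", "E", "A", "Y", "G", "M", "D", "V", "S", "S")
  # short-loop numbering: 102 legitimately absent
  ch <- chain_record("H", "heavy", data.frame(
    res_number = c(92:101, 103L, 104L), icode = "", aa = aa,
    x = 3.8 * (1:12), y = 0, z = 0, stringsAsFactors = FALSE))
  spec <- locate_cdr(ch, "HCDR3")  # residues numbered 95..101
  expect_equal(cdr_sequence(ch, spec), "EAYGMDV")

  one <- cdr_spec("H", "HCDR3", 5L, 5L)
  expect_equal(cdr_sequence(ch, one), "A")

  wide <- cdr_spec("H", "HCDR3", spec$start_idx - 1L, spec$end_idx + 1L,
                   shift = c(-1L, 1L))
  expect_equal(cdr_sequence(ch, wide), paste0("K", "EAYGMDV", "S"))

  oob <- cdr_spec("H", "HCDR3", 10L, 13L)
  expect_error(cdr_sequence(ch, oob), "bounds")
})

test_that("pair dataset building, exclusion and augmentation counts", {
  sp <- toy_spec(n_complexes = 2, seed = 9)
  ds <- make_toy_dataset(sp)
  pairs0 <- build_pair_dataset(ds$complexes, k = 0L, cdr_names = "HCDR3")
  expect_length(pairs0, 2L)  # one per locatable complete CDR

  seq1 <- attr(pairs0, "manifest")$sequence[1]
  pairs_ex <- build_pair_dataset(ds$complexes, k = 0L,
                                 test_cdr_sequences = seq1,
                                 cdr_names = "HCDR3")
  expect_false(seq1 %in% attr(pairs_ex, "manifest")$sequence)

  pairs1 <- build_pair_dataset(ds$complexes[1], k = 1L, cdr_names = "HCDR3")
  expect_length(pairs1, 9L)  # (2*1+1)^2, interior CDR, no clamping
})

test_that("similarity filtering removes near-identical training CDRs", {
  sp <- toy_spec(n_complexes = 2, seed = 9)
  ds <- make_toy_dataset(sp)
  pairs0 <- build_pair_dataset(ds$complexes, k = 0L, cdr_names = "HCDR3")
  seqs <- attr(pairs0, "manifest")$sequence
  # identical sequence has identity 1 >= 0.5 -> removed under strict split
  expect_warning(
    strict <- build_pair_dataset(ds$complexes, k = 0L,
                                 test_cdr_sequences = seqs,
                                 similarity_threshold = 0.5,
                                 cdr_names = "HCDR3"),
    "empty")
  expect_length(strict, 0L)
  # an unrelated test sequence removes nothing
  loose <- build_pair_dataset(ds$complexes, k = 0L,
                              test_cdr_sequences = "WWWWWWW",
                              similarity_threshold = 0.9,
                              cdr_names = "HCDR3")
  expect_length(loose, 2L)
})
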