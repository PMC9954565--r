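test_that("the TNF schedule encodes the published timeline", {
  s <- build_tnf_schedule()
  expect_length(validate_schedule(s), 0)
  rep <- effective_exposures(s)
  # group 1: 20 -> 280 min minus one transition = 240 min
  expect_equal(pcdscreen:::exposure_of(rep, "1", "TNF"), 240)
  # group 2: 230 -> 280 min minus one transition = 30 min
  expect_equal(pcdscreen:::exposure_of(rep, "2", "TNF"), 30)
  # the control group never receives TNF
  expect_equal(pcdscreen:::exposure_of(rep, "3", "TNF"), 0)
  expect_false("TNF" %in% rep$reagent[rep$group == "3"])
  # exposure multiset over groups is {240, 30, 0}
  tnf <- vapply(c("1", "2", "3"),
                function(g) pcdscreen:::exposure_of(rep, g, "TNF"), numeric(1))
  expect_setequal(tnf, c(240, 30, 0))
  # between 230 and 280 min TNF streams on two groups = 6 pixels
  blocks <- pcdscreen:::schedule_blocks(s)
  on_tnf <- vapply(blocks, function(b)
    any(b$reagent == "TNF" & b$start <= 230 & b$stop >= 280), logical(1))
  expect_equal(sum(on_tnf) * 3, 6)
})

test_that("staining schedule phases and rotation behave as specified", {
  s <- build_staining_schedule()
  expect_length(validate_schedule(s), 0)
  expect_equal(s$t_end, 330)   # 20 + 120 + 180 + 10
  rep <- effective_exposures(s)
  for (g in s$groups) {
    dyes <- rep[rep$group == g & !rep$reagent %in% c("medium", "PBS"), ]
    expect_equal(nrow(dyes), 2)              # two distinct colours
    expect_equal(dyes$nominal_min, c(120, 180))
    expect_false(anyDuplicated(dyes$reagent) > 0)
  }
  # identity rotation: one dye for a contiguous 300 min block
  ident <- build_staining_schedule(c(green = "green", red = "red",
                                     blue = "blue"))
  repi <- effective_exposures(ident)
  g_dye <- repi[repi$group == "green" & repi$reagent == "green", ]
  expect_equal(g_dye$nominal_min, 300)       # 120 + 180 interval union
  expect_equal(g_dye$effective_min, 280)     # one transition per block
  expect_error(build_staining_schedule(c(green = "red", red = "red",
                                         blue = "blue")), "bijection")
})

test_that("effective exposure deducts one transition per contiguous block", {
  s <- build_tnf_schedule()
  rep <- effective_exposures(s)
  expect_true(all(rep$effective_min <= rep$nominal_min))
  expect_true(all(rep$effective_min >= 0))
  # zero transition time: effective equals nominal
  s0 <- build_tnf_schedule(transition_time_min = 0)
  rep0 <- effective_exposures(s0)
  expect_equal(rep0$effective_min, rep0$nominal_min)
  # splitting a block by re-asserting the same reagent changes nothing
  ev <- data.frame(time = c(0, 20, 150, 230, 280),
                   group = c("all", "1", "1", "2", "all"),
                   reagent = c("medium", "TNF", "TNF", "TNF", "PBS"))
  s_split <- pcd_schedule(ev, t_end = 300)
  expect_equal(pcdscreen:::exposure_of(effective_exposures(s_split),
                                       "1", "TNF"), 240)
})

test_that("validation reports violations as data", {
  s <- build_tnf_schedule()
  bad <- s
  bad$events$time[4] <- 350            # event after t_end
  expect_length(validate_schedule(bad), 1)
  bad2 <- s
  bad2$events <- rbind(bad2$events,
                       data.frame(time = 20, group = "1", reagent = "PBS"))
  expect_gte(length(validate_schedule(bad2)), 1)
  no_start <- list(events = data.frame(time = 50, group = "1",
                                       reagent = "TNF"),
                   t_end = 100, groups = "1", transition_time_min = 20)
  expect_gte(length(validate_schedule(no_start)), 1)
  expect_error(pcd_schedule(data.frame(time = 0.5, group = "all",
                                       reagent = "x"), t_end = 10),
               "integer minutes")
})

test_that("schedules round-trip through JSON", {
  for (s in list(build_tnf_schedule(), build_staining_schedule())) {
    f <- tempfile(fileext = ".json")
    schedule_to_json(s, f)
    s2 <- schedule_from_json(f)
    expect_equal(s2$events, s$events)
    expect_equal(s2$t_end, s$t_end)
    expect_equal(s2$groups, s$groups)
    expect_equal(s2$transition_time_min, s$transition_time_min)
    expect_equal(effective_exposures(s2), effective_exposures(s))
  }
})
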