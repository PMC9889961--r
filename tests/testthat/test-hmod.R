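test_that("serialize -> parse is the identity on toy models", {
  for (kind in TOY_KINDS) {
    m <- make_toy_model(kind, seed = 9)
    txt <- serialize_hmod(m)
    res <- parse_hmod(txt)
    expect_identical(nrow(res$report), 0L, info = kind)
    back <- res$model
    expect_identical(names(back$species), names(m$species))
    for (s in names(m$species)) {
      expect_identical(back$species[[s]]$init, m$species[[s]]$init)
    }
    for (p in names(m$parameters)) {
      expect_identical(back$parameters[[p]]$value, m$parameters[[p]]$value)
    }
    for (r in names(m$reactions)) {
      expect_true(expr_identical(back$reactions[[r]]$law, m$reactions[[r]]$law))
      expect_identical(back$reactions[[r]]$reactants, m$reactions[[r]]$reactants)
    }
    # canonical form is a fixed point
    expect_identical(serialize_hmod(back), txt)
  }
})

test_that("serialization is byte-deterministic", {
  m <- make_toy_model("michaelis-menten-pathway", seed = 13)
  a <- make_random_ann(c(2, 3, 1), seed = 13,
                       input_ids = c("S", "P"),
                       outputs = data.frame(kind = "reaction-rate", id = "v1",
                                            factor = NA_character_))
  expect_identical(serialize_hmod(m, a), serialize_hmod(m, a))
})

test_that("mechanistic documents carry exactly the blocks they need", {
  m <- make_toy_model("reversible-pair", seed = 3)
  txt <- serialize_hmod(m)
  for (b in c("[COMPARTMENTS]", "[SPECIES]", "[PARAMETERS]", "[REACTIONS]")) {
    expect_match(txt, b, fixed = TRUE)
  }
  expect_no_match(txt, "[ML]", fixed = TRUE)
  expect_no_match(txt, "[RATE_RULES]", fixed = TRUE)
})

test_that("the ml block lists the declared network shape", {
  m <- make_toy_model("michaelis-menten-pathway", seed = 13)
  a <- make_random_ann(c(2, 3, 1), seed = 13, input_ids = c("S", "P"),
                       outputs = data.frame(kind = "reaction-rate", id = "v1",
                                            factor = NA_character_))
  txt <- serialize_hmod(m, a)
  expect_match(txt, "layer_1 : size=3, activation=tanh", fixed = TRUE)
  expect_match(txt, "layer_2 : size=1, activation=linear", fixed = TRUE)
  expect_identical(length(grep("^w_1_", strsplit(txt, "\n")[[1]])), 3L)
  expect_identical(length(grep("^w_2_", strsplit(txt, "\n")[[1]])), 1L)

  res <- parse_hmod(txt)
  expect_identical(nrow(res$report), 0L)
  expect_identical(dim(res$ann$layers[[1]]$W), c(3L, 2L))
  expect_identical(res$ann$layers[[1]]$W, a$layers[[1]]$W)
  expect_identical(res$ann$layers[[2]]$b, a$layers[[2]]$b)
  expect_identical(res$ann$inputs, a$inputs)
})

test_that("definition order is enforced and problems carry their code", {
  bad <- paste(
    "HMOD/1", "model : id=m, name=m",
    "[SPECIES]",
    "A : compartment=cell, init=1, boundary=false, constant=false, name=A",
    "[COMPARTMENTS]", "cell : size=1, constant=true, name=cell",
    sep = "\n")
  rep <- validate_hmod(bad)
  expect_true(any(rep$code == "ORDER_VIOLATION"))
  expect_true(any(rep$code == "DANGLING_REF"))  # species used before cell exists
})

test_that("parse_hmod never throws: fatal problems come back as report rows", {
  res <- parse_hmod("not an hmod file at all")
  expect_null(res$model)
  expect_false(report_ok(res$report))
  expect_true(any(res$report$code == "BAD_HEADER"))
})

test_that("random model + ann pairs round trip through HMOD", {
  for (seed in 1:10) {
    kind <- TOY_KINDS[(seed %% 4) + 1]
    m <- make_toy_model(kind, seed = seed)
    sp <- names(m$species)[1]
    a <- make_random_ann(c(1, 4, 1), seed = seed, input_ids = sp,
                         bounds = data.frame(min = 0, max = 2),
                         outputs = data.frame(kind = "reaction-rate",
                                              id = names(m$reactions)[1],
                                              factor = NA_character_))
    res <- parse_hmod(serialize_hmod(m, a))
    expect_identical(nrow(res$report), 0L)
    expect_identical(res$ann$layers[[1]]$W, a$layers[[1]]$W)
    expect_identical(res$ann$layers[[2]]$W, a$layers[[2]]$W)
    expect_identical(res$ann$layers[[1]]$b, a$layers[[1]]$b)
    expect_identical(res$ann$outputs$id, a$outputs$id)
  }
})
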