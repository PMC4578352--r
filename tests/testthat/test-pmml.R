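# PMML subset: data dictionary, derived-field arithmetic, degenerate cases.

## Fig-21-style document: two zeta potentials in, four internal variables
## out (charge change, relative change, and the two magnitudes).
zetaPMML <- function() {
  paste0(
    '<PMML version="4.2" xmlns="http://www.dmg.org/PMML-4_2">',
    '<DataDictionary numberOfFields="2">',
    '<DataField name="zp_synth" optype="continuous" dataType="double"/>',
    '<DataField name="zp_serum" optype="continuous" dataType="double"/>',
    '</DataDictionary>',
    '<TransformationDictionary>',
    '<DerivedField name="zp_ch" optype="continuous" dataType="double">',
    '<Apply function="-"><FieldRef field="zp_serum"/><FieldRef field="zp_synth"/></Apply>',
    '</DerivedField>',
    '<DerivedField name="zp_rel" optype="continuous" dataType="double">',
    '<Apply function="/"><FieldRef field="zp_ch"/><FieldRef field="zp_synth"/></Apply>',
    '</DerivedField>',
    '<DerivedField name="zp_synth_mag" optype="continuous" dataType="double">',
    '<Apply function="abs"><FieldRef field="zp_synth"/></Apply>',
    '</DerivedField>',
    '<DerivedField name="zp_serum_mag" optype="continuous" dataType="double">',
    '<Apply function="abs"><FieldRef field="zp_serum"/></Apply>',
    '</DerivedField>',
    '</TransformationDictionary>',
    '</PMML>')
}

test_that("a document with abs(a - b) parses to one derived field of depth 2", {
  xml <- paste0(
    '<PMML xmlns="http://www.dmg.org/PMML-4_2">',
    '<DataDictionary>',
    '<DataField name="a" optype="continuous" dataType="double"/>',
    '<DataField name="b" optype="continuous" dataType="double"/>',
    '</DataDictionary>',
    '<TransformationDictionary>',
    '<DerivedField name="d" optype="continuous" dataType="double">',
    '<Apply function="abs"><Apply function="-">',
    '<FieldRef field="a"/><FieldRef field="b"/></Apply></Apply>',
    '</DerivedField>',
    '</TransformationDictionary></PMML>')
  spec <- parsePMML(xml)
  expect_identical(nrow(spec@dataFields), 2L)
  expect_identical(names(spec@derivedFields), "d")
  e <- spec@derivedFields$d
  expect_identical(e$fn, "abs")
  expect_identical(e$args[[1]]$fn, "-")
  tab <- data.frame(a = c(1, 5), b = c(4, 2))
  out <- applySpec(spec, tab)
  expect_identical(out$d, c(3, 3))
})

test_that("empty transformation dictionaries select the data fields", {
  xml <- paste0(
    '<PMML xmlns="http://www.dmg.org/PMML-4_2"><DataDictionary>',
    '<DataField name="x" optype="continuous" dataType="double"/>',
    '</DataDictionary><TransformationDictionary/></PMML>')
  spec <- parsePMML(xml)
  expect_length(spec@derivedFields, 0)
  out <- applySpec(spec, data.frame(x = 1:3, y = 4:6))
  expect_identical(colnames(out), "x")
})

test_that("undeclared references and unsupported functions are named errors", {
  bad <- paste0(
    '<PMML xmlns="http://www.dmg.org/PMML-4_2"><DataDictionary>',
    '<DataField name="a" optype="continuous" dataType="double"/>',
    '</DataDictionary><TransformationDictionary>',
    '<DerivedField name="d" optype="continuous" dataType="double">',
    '<FieldRef field="zp_x"/></DerivedField>',
    '</TransformationDictionary></PMML>')
  err <- tryCatch(parsePMML(bad), error = identity)
  expect_s3_class(err, "enmkit_pmml_error")
  expect_match(conditionMessage(err), "zp_x")

  badFn <- sub('<FieldRef field="zp_x"/>',
               '<Apply function="median"><FieldRef field="a"/></Apply>', bad)
  err2 <- tryCatch(parsePMML(badFn), error = identity)
  expect_s3_class(err2, "enmkit_pmml_error")
  expect_match(conditionMessage(err2), "median")

  ## forward reference to a later derived field
  fwd <- paste0(
    '<PMML xmlns="http://www.dmg.org/PMML-4_2"><DataDictionary>',
    '<DataField name="a" optype="continuous" dataType="double"/>',
    '</DataDictionary><TransformationDictionary>',
    '<DerivedField name="d1" optype="continuous" dataType="double">',
    '<FieldRef field="d2"/></DerivedField>',
    '<DerivedField name="d2" optype="continuous" dataType="double">',
    '<FieldRef field="a"/></DerivedField>',
    '</TransformationDictionary></PMML>')
  expect_error(parsePMML(fwd), "d2", class = "enmkit_pmml_error")
})

test_that("model elements outside the dictionaries are ignored with a notice", {
  xml <- paste0(
    '<PMML xmlns="http://www.dmg.org/PMML-4_2"><DataDictionary>',
    '<DataField name="x" optype="continuous" dataType="double"/>',
    '</DataDictionary>',
    '<RegressionModel functionName="regression"/></PMML>')
  spec <- parsePMML(xml)
  expect_match(spec@notices, "RegressionModel")
})

test_that("division by zero and log faults produce missing cells and log events", {
  spec <- parsePMML(zetaPMML())
  tab <- data.frame(zp_synth = c(-30, 0, 10), zp_serum = c(-10, -10, NA))
  out <- applySpec(spec, tab)
  expect_equal(out$zp_ch, c(20, -10, NA))
  expect_equal(out$zp_rel[1], 20 / -30)
  expect_true(is.na(out$zp_rel[2]))   # division by zero
  expect_true(is.na(out$zp_rel[3]))   # missing input propagates
  expect_match(paste(attr(out, "transformLog"), collapse = "; "),
               "division by zero")

  logSpec <- parsePMML(paste0(
    '<PMML xmlns="http://www.dmg.org/PMML-4_2"><DataDictionary>',
    '<DataField name="x" optype="continuous" dataType="double"/>',
    '</DataDictionary><TransformationDictionary>',
    '<DerivedField name="lx" optype="continuous" dataType="double">',
    '<Apply function="log2"><FieldRef field="x"/></Apply></DerivedField>',
    '</TransformationDictionary></PMML>'))
  out2 <- applySpec(logSpec, data.frame(x = c(8, 0, -1)))
  expect_equal(out2$lx[1], 3)
  expect_true(all(is.na(out2$lx[2:3])))
})

test_that("the four zeta internal variables match an independent recomputation", {
  spec <- parsePMML(zetaPMML())
  set.seed(5)
  tab <- data.frame(zp_synth = round(runif(5, -60, 40), 2),
                    zp_serum = round(runif(5, -30, 5), 2))
  out <- applySpec(spec, tab)
  ## recomputed cell by cell, spreadsheet style
  for (i in 1:5) {
    ch <- tab$zp_serum[i] - tab$zp_synth[i]
    expect_equal(out$zp_ch[i], ch)
    expect_equal(out$zp_rel[i], ch / tab$zp_synth[i])
    expect_equal(out$zp_synth_mag[i], abs(tab$zp_synth[i]))
    expect_equal(out$zp_serum_mag[i], abs(tab$zp_serum[i]))
  }
})

test_that("bare field-ref specs reproduce the input; chained specs compose", {
  idSpec <- parsePMML(paste0(
    '<PMML xmlns="http://www.dmg.org/PMML-4_2"><DataDictionary>',
    '<DataField name="a" optype="continuous" dataType="double"/>',
    '<DataField name="b" optype="continuous" dataType="double"/>',
    '</DataDictionary><TransformationDictionary>',
    '<DerivedField name="a2" optype="continuous" dataType="double">',
    '<FieldRef field="a"/></DerivedField>',
    '<DerivedField name="b2" optype="continuous" dataType="double">',
    '<FieldRef field="b"/></DerivedField>',
    '</TransformationDictionary></PMML>'))
  set.seed(6)
  tab <- data.frame(a = rnorm(10), b = rnorm(10))
  out <- applySpec(idSpec, tab)
  expect_identical(unname(as.matrix(out)), unname(as.matrix(tab)))

  ## g then f as chained specs == composed f(g(x))
  g <- parsePMML(paste0(
    '<PMML xmlns="http://www.dmg.org/PMML-4_2"><DataDictionary>',
    '<DataField name="a" optype="continuous" dataType="double"/>',
    '</DataDictionary><TransformationDictionary>',
    '<DerivedField name="g" optype="continuous" dataType="double">',
    '<Apply function="*"><FieldRef field="a"/><Constant>2</Constant></Apply>',
    '</DerivedField></TransformationDictionary></PMML>'))
  f <- parsePMML(paste0(
    '<PMML xmlns="http://www.dmg.org/PMML-4_2"><DataDictionary>',
    '<DataField name="g" optype="continuous" dataType="double"/>',
    '</DataDictionary><TransformationDictionary>',
    '<DerivedField name="fg" optype="continuous" dataType="double">',
    '<Apply function="+"><FieldRef field="g"/><Constant>1</Constant></Apply>',
    '</DerivedField></TransformationDictionary></PMML>'))
  fg <- parsePMML(paste0(
    '<PMML xmlns="http://www.dmg.org/PMML-4_2"><DataDictionary>',
    '<DataField name="a" optype="continuous" dataType="double"/>',
    '</DataDictionary><TransformationDictionary>',
    '<DerivedField name="g" optype="continuous" dataType="double">',
    '<Apply function="*"><FieldRef field="a"/><Constant>2</Constant></Apply>',
    '</DerivedField>',
    '<DerivedField name="fg" optype="continuous" dataType="double">',
    '<Apply function="+"><FieldRef field="g"/><Constant>1</Constant></Apply>',
    '</DerivedField></TransformationDictionary></PMML>'))
  chained <- applySpec(f, applySpec(g, tab["a"]))
  composed <- applySpec(fg, tab["a"])
  expect_identical(chained$fg, composed$fg)
})

test_that("unmatched data fields list the available columns; aliases resolve them", {
  spec <- parsePMML(zetaPMML())
  tab <- data.frame(`zeta synth (mV)` = c(-30, -20),
                    `zeta serum (mV)` = c(-10, -5), check.names = FALSE)
  err <- tryCatch(applySpec(spec, tab), error = identity)
  expect_s3_class(err, "enmkit_pmml_error")
  expect_match(conditionMessage(err), "zeta synth \\(mV\\)")
  out <- applySpec(spec, tab, alias = c(zp_synth = "zeta synth (mV)",
                                        zp_serum = "zeta serum (mV)"))
  expect_equal(out$zp_ch, c(20, 15))
})

test_that("exported regression PMML re-parses with the declared fields", {
  co <- c(`(Intercept)` = 1.5, x1 = 2, x2 = -3)
  xml <- writePMMLRegression(co, "y")
  spec <- parsePMML(xml)
  expect_setequal(spec@dataFields$name, c("x1", "x2", "y"))
  expect_match(spec@notices, "RegressionModel")
  expect_match(xml, 'intercept="1.5')
})
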