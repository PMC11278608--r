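#' Reference mediation table for regression testing
#'
#' The 69 mediators selected by the reference two-step MR analysis of type 2
#' diabetes on calcific aortic valve stenosis, with their published
#' exposure-to-mediator effects (`b1`), mediator-to-outcome effects (`b2`),
#' indirect effects (`prod = b1 * b2`) with delta-method confidence intervals,
#' and proportions mediated (percent of the total effect, `log(1.153)` on the
#' log-odds scale). Values are point estimates rounded to the printed
#' precision; `*_dp` columns record the printed decimal places so tests can
#' reason about rounding slack.
#'
#' @return data.frame with 69 rows and columns `category, mediator, b1,
#'   b1_lo, b1_hi, b2, b2_lo, b2_hi, prod, prod_lo, prod_hi, prop_pct` plus
#'   `prod_dp`, `prop_dp`; the total effect is attached as
#'   `attr(, "total_beta") = log(1.153)` and `attr(, "total_or") = 1.153`.
#' @export
table1_fixture <- function() {
  txt <- c(
    "Amino acids	Total_BCAA	0.075	0.056	0.093	0.445	0.054	0.837	0.033	0.003	0.064	23.288",
    "Amino acids	Tyr	0.051	0.031	0.071	0.271	0.081	0.461	0.014	0.002	0.025	9.684",
    "Amino acids	Val	0.075	0.056	0.093	0.340	0.022	0.658	0.025	0.001	0.050	17.782",
    "Blood pressure	SBP	0.541	0.366	0.716	0.023	0.016	0.030	0.012	0.007	0.018	8.716",
    "Cholesterol	L_HDL_CE_pct	-0.068	-0.089	-0.047	-0.155	-0.299	-0.012	0.011	0.000	0.021	7.408",
    "Cholesterol	L_VLDL_C	0.040	0.019	0.061	0.255	0.109	0.402	0.010	0.002	0.018	7.158",
    "Cholesterol	L_VLDL_CE	0.027	0.006	0.048	0.324	0.180	0.469	0.009	0.001	0.017	6.094",
    "Cholesterol	L_VLDL_FC	0.052	0.030	0.074	0.274	0.132	0.416	0.014	0.005	0.024	9.965",
    "Cholesterol	M_HDL_C_pct	-0.057	-0.077	-0.036	-0.191	-0.319	-0.062	0.011	0.002	0.019	7.556",
    "Cholesterol	M_HDL_CE_pct	-0.055	-0.077	-0.034	-0.214	-0.335	-0.092	0.012	0.004	0.020	8.278",
    "Cholesterol	M_LDL_FC_pct	-0.075	-0.095	-0.055	-0.158	-0.274	-0.042	0.012	0.003	0.021	8.3",
    "Cholesterol	S_HDL_C_pct	-0.052	-0.072	-0.031	-0.156	-0.294	-0.019	0.008	0.000	0.016	5.656",
    "Cholesterol	S_HDL_CE_pct	-0.044	-0.064	-0.024	-0.208	-0.340	-0.076	0.009	0.002	0.016	6.419",
    "Cholesterol	S_LDL_CE_pct	0.025	0.007	0.044	0.205	0.077	0.334	0.005	0.000	0.010	3.642",
    "Cholesterol	S_LDL_FC_pct	-0.069	-0.089	-0.049	-0.171	-0.284	-0.059	0.012	0.003	0.020	8.279",
    "Cholesterol	VLDL_FC	0.028	0.006	0.049	0.309	0.176	0.442	0.009	0.001	0.016	6.033",
    "Cholesterol	XL_VLDL_C	0.044	0.024	0.064	0.317	0.169	0.465	0.014	0.005	0.023	9.804",
    "Cholesterol	XL_VLDL_CE	0.027	0.006	0.048	0.264	0.120	0.408	0.007	0.000	0.014	5.004",
    "Cholesterol	XL_VLDL_FC	0.056	0.035	0.077	0.296	0.152	0.440	0.016	0.006	0.027	11.564",
    "Cholesterol	XXL_VLDL_C	0.061	0.040	0.081	0.259	0.115	0.402	0.016	0.005	0.026	11.001",
    "Cholesterol	XXL_VLDL_CE	0.058	0.037	0.079	0.254	0.126	0.383	0.015	0.005	0.024	10.327",
    "Cholesterol	XXL_VLDL_FC	0.065	0.044	0.085	0.202	0.059	0.345	0.013	0.003	0.023	9.16",
    "Fatty acids	MUFA	0.047	0.026	0.067	0.305	0.164	0.446	0.014	0.005	0.023	9.972",
    "Fatty acids	MUFA_pct	0.062	0.041	0.083	0.201	0.049	0.353	0.013	0.002	0.023	8.764",
    "Fatty acids	Omega_3	0.022	0.004	0.040	0.312	0.218	0.407	0.007	0.001	0.013	4.783",
    "Fatty acids	Omega_6_by_Omega_3	-0.031	-0.048	-0.013	-0.373	-0.524	-0.222	0.011	0.003	0.020	8.052",
    "Fatty acids	Omega_6_pct	-0.062	-0.083	-0.040	-0.297	-0.473	-0.120	0.018	0.005	0.031	12.821",
    "Fatty acids	SFA	0.028	0.008	0.047	0.331	0.164	0.498	0.009	0.001	0.017	6.39",
    "Fatty acids	SFA_pct	0.031	0.013	0.050	0.454	0.131	0.777	0.014	0.001	0.028	9.901",
    "Fatty acids	Total_FA	0.026	0.008	0.044	0.290	0.149	0.430	0.008	0.001	0.014	5.331",
    "Lipoprptein particle concentration	L_VLDL_P	0.058	0.037	0.079	0.287	0.140	0.435	0.017	0.006	0.027	11.672",
    "Lipoprptein particle concentration	S_VLDL_P	0.028	0.008	0.048	0.276	0.149	0.403	0.008	0.001	0.014	5.389",
    "Lipoprptein particle concentration	VLDL_P	0.023	0.003	0.044	0.326	0.197	0.455	0.008	0.000	0.015	5.355",
    "Lipoprptein particle concentration	XL_VLDL_P	0.062	0.041	0.084	0.276	0.150	0.403	0.017	0.007	0.027	12.049",
    "Lipoprptein particle concentration	XXL_VLDL_P	0.067	0.046	0.088	0.246	0.103	0.389	0.017	0.006	0.028	11.605",
    "Phospholipids	L_VLDL_PL	0.057	0.036	0.077	0.269	0.134	0.404	0.015	0.006	0.025	10.668",
    "Phospholipids	L_VLDL_PL_pct	0.036	0.015	0.057	0.227	0.097	0.356	0.008	0.001	0.015	5.748",
    "Phospholipids	S_LDL_PL_pct	-0.033	-0.052	-0.014	-0.212	-0.346	-0.077	0.007	0.001	0.013	4.917",
    "Phospholipids	VLDL_PL	0.028	0.007	0.049	0.287	0.153	0.421	0.008	0.001	0.015	5.629",
    "Phospholipids	XL_VLDL_PL	0.058	0.037	0.079	0.281	0.139	0.423	0.016	0.006	0.027	11.401",
    "Phospholipids	XXL_VLDL_PL	0.068	0.047	0.089	0.221	0.073	0.369	0.015	0.004	0.026	10.547",
    "Phospholipids	XXL_VLDL_PL_pct	0.035	0.017	0.053	0.217	0.062	0.372	0.008	0.001	0.014	5.357",
    "Total lipids	L_VLDL_L	0.058	0.037	0.079	0.292	0.138	0.447	0.017	0.006	0.028	11.828",
    "Total lipids	S_VLDL_L	0.025	0.005	0.044	0.280	0.154	0.407	0.007	0.001	0.013	4.88",
    "Total lipids	VLDL_L	0.044	0.024	0.064	0.314	0.175	0.452	0.014	0.005	0.023	9.725",
    "Total lipids	XL_VLDL_L	0.062	0.041	0.084	0.281	0.151	0.411	0.018	0.007	0.028	12.282",
    "Total lipids	XXL_VLDL_L	0.066	0.045	0.087	0.192	0.033	0.351	0.013	0.001	0.024	8.885",
    "Triglycerides	HDL_TG	0.048	0.030	0.066	0.227	0.131	0.324	0.011	0.005	0.017	7.641",
    "Triglycerides	IDL_TG	0.035	0.016	0.054	0.249	0.118	0.381	0.009	0.002	0.015	6.066",
    "Triglycerides	L_HDL_TG_pct	0.059	0.040	0.079	0.184	0.075	0.293	0.011	0.003	0.018	7.646",
    "Triglycerides	L_LDL_TG	0.036	0.017	0.055	0.258	0.129	0.387	0.009	0.003	0.016	6.56",
    "Triglycerides	L_VLDL_TG	0.064	0.042	0.085	0.257	0.105	0.409	0.016	0.005	0.028	11.521",
    "Triglycerides	LDL_TG	0.039	0.020	0.058	0.253	0.131	0.375	0.010	0.003	0.017	6.938",
    "Triglycerides	M_HDL_TG	0.052	0.033	0.070	0.214	0.116	0.313	0.011	0.005	0.018	7.761",
    "Triglycerides	M_HDL_TG_pct	0.051	0.031	0.071	0.187	0.067	0.308	0.010	0.002	0.017	6.692",
    "Triglycerides	M_LDL_TG	0.044	0.024	0.064	0.247	0.117	0.377	0.011	0.003	0.019	7.594",
    "Triglycerides	M_VLDL_TG	0.052	0.030	0.073	0.303	0.167	0.440	0.016	0.006	0.025	10.969",
    "Triglycerides	S_HDL_TG	0.063	0.043	0.083	0.218	0.107	0.329	0.014	0.005	0.022	9.624",
    "Triglycerides	S_HDL_TG_pct	0.057	0.036	0.078	0.173	0.061	0.284	0.010	0.002	0.017	6.883",
    "Triglycerides	S_LDL_TG	0.055	0.035	0.076	0.276	0.145	0.406	0.015	0.006	0.024	10.664",
    "Triglycerides	S_LDL_TG_pct	0.074	0.052	0.095	0.165	0.031	0.299	0.012	0.002	0.023	8.51",
    "Triglycerides	S_VLDL_TG	0.059	0.037	0.080	0.235	0.124	0.346	0.014	0.005	0.022	9.637",
    "Triglycerides	TG_by_PG	0.067	0.046	0.088	0.161	0.037	0.285	0.011	0.002	0.020	7.526",
    "Triglycerides	Total_TG	0.061	0.040	0.081	0.282	0.155	0.408	0.017	0.007	0.027	11.989",
    "Triglycerides	VLDL_TG	0.063	0.042	0.084	0.260	0.129	0.392	0.016	0.006	0.026	11.485",
    "Triglycerides	XL_HDL_TG_pct	0.065	0.045	0.085	0.198	0.081	0.316	0.013	0.004	0.022	9.035",
    "Triglycerides	XL_VLDL_TG	0.070	0.048	0.092	0.232	0.092	0.372	0.016	0.005	0.027	11.372",
    "Triglycerides	XS_VLDL_TG	0.045	0.024	0.065	0.217	0.092	0.342	0.010	0.002	0.017	6.813",
    "Triglycerides	XXL_VLDL_TG	0.067	0.046	0.089	0.186	0.014	0.359	0.013	0.000	0.025	8.785"
  )
  tab <- utils::read.delim(text = paste(txt, collapse = "\n"), header = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  names(tab) <- c("category", "mediator", "b1", "b1_lo", "b1_hi",
                  "b2", "b2_lo", "b2_hi", "prod", "prod_lo", "prod_hi",
                  "prop_pct")
  dp <- function(s) {
    has <- grepl("\\.", s)
    ifelse(has, nchar(sub("^[^.]*\\.", "", s)), 0L)
  }
  tab$prod_dp <- dp(tab$prod)
  tab$prop_dp <- dp(tab$prop_pct)
  num <- setdiff(names(tab), c("category", "mediator", "prod_dp", "prop_dp"))
  tab[num] <- lapply(tab[num], as.numeric)
  attr(tab, "total_or") <- 1.153
  attr(tab, "total_beta") <- log(1.153)
  tab
}
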