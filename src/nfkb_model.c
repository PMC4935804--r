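/* Two-compartment NF-kB / IkBa model with a cytokine-specific IKKK module
 * under A20 feedback inhibition, for use with deSolve's compiled-model
 * interface.
 *
 * State vector (molecules per cell):
 *   y[0]  IKKKa_T   active IKKK, TNF branch
 *   y[1]  IKKKi_T   inactive IKKK, TNF branch
 *   y[2]  IKKKa_I   active IKKK, IL-1 branch
 *   y[3]  IKKKi_I   inactive IKKK, IL-1 branch
 *   y[4]  IKKa      active IKK
 *   y[5]  IKKi      inactive IKK
 *   y[6]  RmI       IkBa mRNA
 *   y[7]  RmA       A20 mRNA
 *   y[8]  A20       A20 protein
 *   y[9]  IkBc      free cytoplasmic IkBa
 *   y[10] IkBn      free nuclear IkBa
 *   y[11] NFKBc     free cytoplasmic NF-kB
 *   y[12] NFKBn     free nuclear NF-kB
 *   y[13] Cc        cytoplasmic NF-kB:IkBa complex
 *   y[14] Cn        nuclear NF-kB:IkBa complex
 *
 * Neutral pools are implicit (conservation by construction):
 *   IKKKn_X = IKKKtott_X - IKKKa_X - IKKKi_X
 *   IKKn    = IKKtot - IKKa - IKKi
 *   total NF-kB = NFKBc + NFKBn + Cc + Cn = nfkbtot (invariant of the flux
 *   scheme; nfkbtot enters only through the initial condition)
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define N_SCALAR 44
#define MAX_PULSES 8
#define N_PARMS (N_SCALAR + 1 + 4 * MAX_PULSES)

static double parms[N_PARMS];

/* scalar parameter slots; order must match .parms_order in R/params.R */
#define P_ka_T       parms[0]
#define P_ka_I       parms[1]
#define P_ki         parms[2]
#define P_m3         parms[3]
#define P_kA20_T     parms[4]
#define P_kA20_I     parms[5]
#define P_IKKKtott_T parms[6]
#define P_IKKKtott_I parms[7]
#define P_kact       parms[8]
#define P_sIKKK      parms[9]
#define P_k1         parms[10]
#define P_k4         parms[11]
#define P_IKKtot     parms[12]
#define P_c1a        parms[13]
#define P_c3a        parms[14]
#define P_c2a        parms[15]
#define P_c4a        parms[16]
#define P_c1         parms[17]
#define P_c3         parms[18]
#define P_c2         parms[19]
#define P_c4         parms[20]
#define P_KN         parms[21]
#define P_hill_tr    parms[22]
#define P_hill_ikk   parms[23]
#define P_b0         parms[24]
#define P_kb         parms[25]
#define P_kc1        parms[26]
#define P_kc2        parms[27]
#define P_Km_ikk     parms[28]
#define P_c5         parms[29]
#define P_iN         parms[30]
#define P_iI         parms[31]
#define P_eI         parms[32]
#define P_eC         parms[33]
#define P_nfkbtot    parms[34]
#define P_Kd_T       parms[35]
#define P_hd_T       parms[36]
#define P_Kd_I       parms[37]
#define P_hd_I       parms[38]
#define P_tau_w      parms[39]
#define P_gate_I     parms[40]  /* IkBa gene state (0/1); 1 = deterministic */
#define P_gate_A     parms[41]
#define P_boost_I    parms[42]  /* telegraph-gene on-state boost koff/kon;
                                 * 0 = deterministic transcription */
#define P_boost_A    parms[43]
#define P_npulses    parms[N_SCALAR]
/* pulse i: start, end, dose, branch (0 = TNF, 1 = IL-1) */
#define PULSE(i, j)  parms[N_SCALAR + 1 + 4 * (i) + (j)]

void nfkb_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

/* receptor signal in [0,1]: Hill dose response during a pulse, exponential
 * washout (time constant tau_w) afterwards; max over that branch's pulses */
static double receptor_tr(double t, int branch)
{
    int np = (int) P_npulses;
    double kd = branch == 0 ? P_Kd_T : P_Kd_I;
    double hd = branch == 0 ? P_hd_T : P_hd_I;
    double s = 0.0;
    for (int i = 0; i < np && i < MAX_PULSES; i++) {
        if ((int) PULSE(i, 3) != branch) continue;
        double start = PULSE(i, 0), end = PULSE(i, 1), dose = PULSE(i, 2);
        if (t < start || dose <= 0.0) continue;
        double dh = pow(dose, hd);
        double phi = dh / (dh + pow(kd, hd));
        double v = (t < end) ? phi : phi * exp(-(t - end) / P_tau_w);
        if (v > s) s = v;
    }
    return s;
}

void nfkb_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double IKKKa_T = y[0], IKKKi_T = y[1], IKKKa_I = y[2], IKKKi_I = y[3];
    double IKKa = y[4], IKKi = y[5];
    double RmI = y[6], RmA = y[7], A20 = y[8];
    double IkBc = y[9], IkBn = y[10];
    double NFKBc = y[11], NFKBn = y[12], Cc = y[13], Cn = y[14];

    double IKKKn_T = P_IKKKtott_T - IKKKa_T - IKKKi_T;
    double IKKKn_I = P_IKKKtott_I - IKKKa_I - IKKKi_I;
    double IKKn = P_IKKtot - IKKa - IKKi;
    if (IKKKn_T < 0.0) IKKKn_T = 0.0;
    if (IKKKn_I < 0.0) IKKKn_I = 0.0;
    if (IKKn < 0.0) IKKn = 0.0;

    double inh_T = P_kA20_T / (P_kA20_T + A20);
    double inh_I = P_kA20_I / (P_kA20_I + A20);
    double ra_T = P_ka_T * receptor_tr(*t, 0) * IKKKn_T * inh_T;
    double ra_I = P_ka_I * receptor_tr(*t, 1) * IKKKn_I * inh_I;

    ydot[0] = ra_T - P_ki * IKKKa_T;
    ydot[1] = P_ki * IKKKa_T - P_m3 * IKKKi_T;
    ydot[2] = ra_I - P_ki * IKKKa_I;
    ydot[3] = P_ki * IKKKa_I - P_m3 * IKKKi_I;

    double KKa = IKKKa_T + IKKKa_I;
    double kh = pow(KKa, P_hill_ikk);
    double hikk = kh / (pow(P_sIKKK, P_hill_ikk) + kh);
    ydot[4] = P_kact * IKKn * hikk - P_k1 * IKKa;
    ydot[5] = P_k1 * IKKa - P_k4 * IKKi;

    double Nn = NFKBn > 0.0 ? NFKBn : 0.0;
    double nh = pow(Nn, P_hill_tr);
    double hN = nh / (pow(P_KN, P_hill_tr) + nh);
    double drive = P_b0 + (1.0 - P_b0) * hN;

    ydot[6] = P_gate_I * P_c1a * (drive + P_boost_I) - P_c3a * RmI;
    ydot[7] = P_gate_A * P_c1 * (drive + P_boost_A) - P_c3 * RmA;
    ydot[8] = P_c2 * RmA - P_c4 * A20;

    double assoc_c = P_kb * NFKBc * IkBc;
    double assoc_n = P_kb * NFKBn * IkBn;
    /* IKKa acts as a saturable enzyme on cytoplasmic IkBa; free and
     * complexed IkBa are processed as independent saturable substrate
     * pools, and the near-zero-order kinetics on the complex provide the
     * switch that drives relaxation oscillations */
    double deg_free = P_kc2 * IKKa * IkBc / (P_Km_ikk + IkBc);
    double rel_c = P_kc1 * IKKa * Cc / (P_Km_ikk + Cc) + P_c5 * Cc;

    ydot[9]  = P_c2a * RmI - P_c4a * IkBc - deg_free
               - assoc_c + P_eI * IkBn - P_iI * IkBc;
    ydot[10] = P_iI * IkBc - P_eI * IkBn - P_c4a * IkBn - assoc_n;
    ydot[11] = rel_c - assoc_c - P_iN * NFKBc;
    ydot[12] = P_iN * NFKBc - assoc_n;
    ydot[13] = assoc_c + P_eC * Cn - rel_c;
    ydot[14] = assoc_n - P_eC * Cn;

    if (ip[0] >= 2) {
        yout[0] = receptor_tr(*t, 0);
        yout[1] = receptor_tr(*t, 1);
    }
}

static const R_CMethodDef cMethods[] = {
    {"nfkb_initmod", (DL_FUNC) &nfkb_initmod, 1},
    {"nfkb_derivs",  (DL_FUNC) &nfkb_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_nfkbpulse(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
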