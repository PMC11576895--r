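/* Compiled right-hand side of the mPBPK model, used through deSolve's
 * compiled-model interface.  Mirrors R/ode.R::ode_rhs exactly; the packed
 * parameter order must match R/params.R::pvec_names(). */

#include <R.h>
#include <math.h>

#define NPAR 60
static double parms[NPAR];

#define V_p       parms[0]
#define V_ep      parms[1]
#define V_L       parms[2]
/* per-tissue blocks accessed by index below:
 * tissue 1: V_v 3, V_e 4, V_is 5, Q 6, L 7
 * tissue 2: V_v 8, V_e 9, V_is 10, Q 11, L 12 */
#define L_total   parms[13]
#define sigma_L   parms[14]
#define k_up      parms[15]
#define k_up_p    parms[16]
/* S_pino1 17, S_pino2 18 */
#define f_up_v    parms[19]
#define CL_rec_p  parms[20]
/* CL_rec1 21, CL_rec2 22 */
#define f_rec_v   parms[23]
#define k_deg     parms[24]
#define CL_cat_p  parms[25]
/* CL_cat1 26, CL_cat2 27 */
#define FcRn_tot  parms[28]
#define k1on      parms[29]
#define k1off     parms[30]
#define kon       parms[31]
#define koff      parms[32]
#define keon      parms[33]
#define keoff     parms[34]
#define K_p       parms[35]
#define konN      parms[36]
#define koffN     parms[37]
#define Rm_tot    parms[38]
#define CL_renal  parms[39]
#define T_s0      parms[40]
#define k_Ts      parms[41]
#define T_m0      parms[42]
#define k_p_Tm    parms[43]
#define k_int     parms[44]
/* two-pore slots: tissue 1 Js 45 Jl 46 sig_s 47 sig_l 48 PS_s 49 PS_l 50
 *                 tissue 2 Js 51 Jl 52 sig_s 53 sig_l 54 PS_s 55 PS_l 56 */
#define has_Ts    parms[57]
#define has_Tm    parms[58]
#define has_NSB   parms[59]

void mpbpk_initmod(void (* odeparms)(int *, double *))
{
    int N = NPAR;
    odeparms(&N, parms);
}

/* Patlak convection-diffusion flux through one pore class, with analytic
 * small-Pe limit and stable large-|Pe| branches. */
static double patlak(double Cv, double Cis, double J, double sigma, double PS)
{
    double conv = J * (1.0 - sigma), Pe;
    if (PS <= 0.0) {
        if (conv == 0.0) return 0.0;
        return conv > 0.0 ? conv * Cv : conv * Cis;
    }
    Pe = conv / PS;
    if (fabs(Pe) < 1e-8) return PS * (Cv - Cis);
    if (Pe > 500.0) return conv * Cv;
    if (Pe < -500.0) return conv * Cis;
    return conv * (Cv - Cis * exp(-Pe)) / (1.0 - exp(-Pe));
}

void mpbpk_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    const double hTs = has_Ts, hTm = has_Tm, hN = has_NSB;
    const double CLup_p = k_up_p * V_ep;
    double A_p = y[0], Ts_p = y[1], ATs_p = y[2];
    double A_ep = y[3], Ts_ep = y[4], ATs_ep = y[5];
    double F_ep = y[6], AF_ep = y[7], ATF_ep = y[8];
    double A_L = y[9], ATs_L = y[10];
    double sumQ = 0, ven_A = 0, ven_ATs = 0, QTs = 0, lym_A = 0, lym_ATs = 0;
    int i;

    for (i = 0; i < 2; i++) {
        int o = 11 + i * 14;
        double V_v  = parms[3 + i * 5], V_e = parms[4 + i * 5];
        double V_is = parms[5 + i * 5], Q = parms[6 + i * 5], L = parms[7 + i * 5];
        double S_pino = parms[17 + i];
        double CLrec = parms[21 + i], CLcat = parms[26 + i];
        double Js = parms[45 + i * 6], Jl = parms[46 + i * 6];
        double ss = parms[47 + i * 6], sl = parms[48 + i * 6];
        double PSs = parms[49 + i * 6], PSl = parms[50 + i * 6];
        double renal = (i == 1) ? CL_renal : 0.0;
        double A_v = y[o], Ts_v = y[o + 1], ATs_v = y[o + 2];
        double Tm_v = y[o + 3], ATm_v = y[o + 4], ARm_v = y[o + 5];
        double A_e = y[o + 6], Ts_e = y[o + 7], ATs_e = y[o + 8];
        double F_e = y[o + 9], AF_e = y[o + 10], ATF_e = y[o + 11];
        double A_is = y[o + 12], ATs_is = y[o + 13];
        double CLup = S_pino * k_up * V_e;
        double TPA = patlak(A_v, A_is, Js, ss, PSs) + patlak(A_v, A_is, Jl, sl, PSl);
        double TPATs = patlak(ATs_v, ATs_is, Js, ss, PSs) +
                       patlak(ATs_v, ATs_is, Jl, sl, PSl);
        double V_is_eff = K_p * V_is;
        double ksyn = T_s0 * (k_Ts + f_up_v * CLup / V_v);

        ydot[o] = (Q * A_p - (Q - L) * A_v - TPA - f_up_v * CLup * A_v +
                   f_rec_v * CLrec * AF_e - renal * A_v) / V_v -
                  hTs * (kon * A_v * Ts_v - koff * ATs_v) -
                  hTm * (kon * A_v * Tm_v - koff * ATm_v) -
                  hN * (konN * A_v * (Rm_tot - ARm_v) - koffN * ARm_v);
        ydot[o + 1] = hTs * ((Q * (Ts_p - Ts_v) - f_up_v * CLup * Ts_v) / V_v +
                             ksyn - k_Ts * Ts_v - kon * A_v * Ts_v + koff * ATs_v);
        ydot[o + 2] = hTs * ((Q * ATs_p - (Q - L) * ATs_v - TPATs -
                              f_up_v * CLup * ATs_v + f_rec_v * CLrec * ATF_e -
                              renal * ATs_v) / V_v +
                             kon * A_v * Ts_v - koff * ATs_v);
        ydot[o + 3] = hTm * (T_m0 * k_p_Tm - k_p_Tm * Tm_v -
                             kon * A_v * Tm_v + koff * ATm_v);
        ydot[o + 4] = hTm * (kon * A_v * Tm_v - koff * ATm_v - k_int * ATm_v);
        ydot[o + 5] = hN * (konN * A_v * (Rm_tot - ARm_v) - koffN * ARm_v -
                            S_pino * k_up * ARm_v);
        ydot[o + 6] = CLup * (f_up_v * A_v + (1 - f_up_v) * A_is) / V_e -
                      k_deg * A_e - k1on * A_e * F_e + k1off * AF_e -
                      hTs * (keon * A_e * Ts_e - keoff * ATs_e);
        ydot[o + 7] = hTs * (f_up_v * CLup * Ts_v / V_e - CLcat * Ts_e / V_e -
                             keon * A_e * Ts_e + keoff * ATs_e);
        ydot[o + 8] = hTs * (CLup * (f_up_v * ATs_v + (1 - f_up_v) * ATs_is) / V_e +
                             keon * A_e * Ts_e - keoff * ATs_e -
                             k1on * ATs_e * F_e + k1off * ATF_e - CLcat * ATs_e / V_e);
        ydot[o + 9] = -k1on * A_e * F_e + k1off * AF_e + CLrec * AF_e / V_e +
                      hTs * (-k1on * ATs_e * F_e + k1off * ATF_e +
                             CLrec * ATF_e / V_e);
        ydot[o + 10] = k1on * A_e * F_e - k1off * AF_e - CLrec * AF_e / V_e;
        ydot[o + 11] = hTs * (k1on * ATs_e * F_e - k1off * ATF_e -
                              CLrec * ATF_e / V_e);
        ydot[o + 12] = (TPA - L * (1 - sigma_L) * A_is -
                        (1 - f_up_v) * CLup * A_is +
                        (1 - f_rec_v) * CLrec * AF_e) / V_is_eff;
        ydot[o + 13] = hTs * (TPATs - L * (1 - sigma_L) * ATs_is -
                              (1 - f_up_v) * CLup * ATs_is +
                              (1 - f_rec_v) * CLrec * ATF_e) / V_is_eff;

        sumQ += Q;
        ven_A += (Q - L) * A_v;
        ven_ATs += (Q - L) * ATs_v;
        QTs += Q * (Ts_v - Ts_p);
        lym_A += L * (1 - sigma_L) * A_is;
        lym_ATs += L * (1 - sigma_L) * ATs_is;
    }

    {
        double ksyn_p = T_s0 * (k_Ts + CLup_p / V_p);
        ydot[0] = (-sumQ * A_p + ven_A + L_total * A_L - CLup_p * A_p +
                   CL_rec_p * AF_ep) / V_p -
                  hTs * (kon * A_p * Ts_p - koff * ATs_p);
        ydot[1] = hTs * ((QTs - CLup_p * Ts_p) / V_p + ksyn_p - k_Ts * Ts_p -
                         kon * A_p * Ts_p + koff * ATs_p);
        ydot[2] = hTs * ((-sumQ * ATs_p + ven_ATs + L_total * ATs_L -
                          CLup_p * ATs_p + CL_rec_p * ATF_ep) / V_p +
                         kon * A_p * Ts_p - koff * ATs_p);
        ydot[3] = CLup_p * A_p / V_ep - k_deg * A_ep -
                  k1on * A_ep * F_ep + k1off * AF_ep -
                  hTs * (keon * A_ep * Ts_ep - keoff * ATs_ep);
        ydot[4] = hTs * (CLup_p * Ts_p / V_ep - CL_cat_p * Ts_ep / V_ep -
                         keon * A_ep * Ts_ep + keoff * ATs_ep);
        ydot[5] = hTs * (CLup_p * ATs_p / V_ep + keon * A_ep * Ts_ep -
                         keoff * ATs_ep - k1on * ATs_ep * F_ep + k1off * ATF_ep -
                         CL_cat_p * ATs_ep / V_ep);
        ydot[6] = -k1on * A_ep * F_ep + k1off * AF_ep + CL_rec_p * AF_ep / V_ep +
                  hTs * (-k1on * ATs_ep * F_ep + k1off * ATF_ep +
                         CL_rec_p * ATF_ep / V_ep);
        ydot[7] = k1on * A_ep * F_ep - k1off * AF_ep - CL_rec_p * AF_ep / V_ep;
        ydot[8] = hTs * (k1on * ATs_ep * F_ep - k1off * ATF_ep -
                         CL_rec_p * ATF_ep / V_ep);
        ydot[9] = (lym_A - L_total * A_L) / V_L;
        ydot[10] = hTs * (lym_ATs - L_total * ATs_L) / V_L;
    }
}
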