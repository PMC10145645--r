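#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent with soft-thresholding on the centered
// second-moment (covariance) form of the LASSO objective
//   (1/2) beta' G beta - q' beta + lambda ||beta||_1,
// warm-started along a decreasing lambda path. Mirrors the pure-R
// single-lambda solver: full sweeps establish the active set, inner sweeps
// iterate it to tolerance, and the sweep cap is a stopping rule.

static inline double soft(double z, double g){double a=std::fabs(z)-g; if(a<=0) return 0.0; return z>0?a:-a;}
// [[Rcpp::export(name = ".cd_path_cpp")]]
List cd_path_cpp(NumericMatrix Gm, NumericVector qv, NumericVector lambdas, double tol, int max_sweeps, NumericVector beta0){
  const int p=qv.size(), L=lambdas.size();
  std::vector<double> G(Gm.begin(), Gm.end()), q(qv.begin(), qv.end());
  std::vector<double> beta(beta0.begin(), beta0.end());
  NumericMatrix B(p,L); IntegerVector sw(L); LogicalVector cv(L);
  std::vector<int> act; act.reserve(p);
  for(int l=0;l<L;++l){
    const double lam=lambdas[l]; int sweeps=0; bool conv=false;
    while(true){
      ++sweeps; double delta=0;
      for(int j=0;j<p;++j){
        const double gjj=G[j+p*j]; if(gjj==0) continue;
        const double bo=beta[j]; double rho=q[j];
        const double* gj=&G[j]; // row j entries at stride p (col-major)
        for(int k=0;k<p;++k) rho-=gj[p*k]*beta[k];
        rho+=gjj*bo;
        const double bn=soft(rho,lam)/gjj;
        if(bn!=bo){beta[j]=bn; double d=std::fabs(bn-bo); if(d>delta)delta=d;}
      }
      if(delta<tol){conv=true;break;}
      if(sweeps>=max_sweeps)break;
      act.clear(); for(int j=0;j<p;++j) if(beta[j]!=0) act.push_back(j);
      while(true){
        ++sweeps; double d2=0;
        for(size_t a=0;a<act.size();++a){int j=act[a];
          const double gjj=G[j+p*j]; if(gjj==0)continue;
          const double bo=beta[j]; double rho=q[j];
          const double* gj=&G[j];
          for(int k=0;k<p;++k) rho-=gj[p*k]*beta[k];
          rho+=gjj*bo;
          const double bn=soft(rho,lam)/gjj;
          if(bn!=bo){beta[j]=bn; double d=std::fabs(bn-bo); if(d>d2)d2=d;}
        }
        if(d2<tol||sweeps>=max_sweeps)break;
      }
      if(sweeps>=max_sweeps)break;
    }
    for(int j=0;j<p;++j)B(j,l)=beta[j];
    sw[l]=sweeps; cv[l]=conv;
  }
  return List::create(_["beta"]=B,_["sweeps"]=sw,_["converged"]=cv);
}
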